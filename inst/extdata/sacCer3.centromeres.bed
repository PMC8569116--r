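chrI	151465	151582	CEN1
chrII	238207	238323	CEN2
chrIII	114385	114501	CEN3
chrIV	449711	449821	CEN4
chrV	151987	152104	CEN5
chrVI	148510	148627	CEN6
chrVII	496920	497038	CEN7
chrVIII	105586	105703	CEN8
chrIX	355629	355745	CEN9
chrX	436307	436425	CEN10
chrXI	440129	440246	CEN11
chrXII	150828	150947	CEN12
chrXIII	268031	268149	CEN13
chrXIV	628758	628875	CEN14
chrXV	326584	326702	CEN15
chrXVI	555957	556073	CEN16
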