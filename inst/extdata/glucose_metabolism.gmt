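glycolysis	glycolytic pathway enzymes	Hk	Gpi	Aldoc	Gapdh	Tpi	Pgk1	Pgam1	Eno1	Eno2	Pk	Pkm2
tca	TCA cycle enzymes	Pdha1	Aco2	Idh	Ogdh	Sdh	Mdh2
etc	electron transport chain / ATP synthesis	Atp5a1	Atp5b	Cox	MT-ND2	Cyc1
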