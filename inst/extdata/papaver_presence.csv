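species,reticuline,salutaridine,salutaridinol,salutaridinol_7_O_acetate,thebaine,oripavine,codeine,morphine
Papaver setigerum,ND,ND,ND,ND,+,ND,+,+
Papaver somniferum,+,ND,ND,ND,+,ND,+,+
Papaver rhoeas,ND,ND,ND,ND,ND,ND,ND,ND
Papaver dubium,ND,ND,ND,ND,ND,ND,ND,ND
Papaver armeniacum,+,+,ND,ND,ND,ND,ND,ND
Papaver triniifolium,+,+,ND,ND,ND,ND,ND,ND
Papaver bracteatum,+,+,ND,ND,+,ND,ND,ND
Papaver orientale,+,+,ND,ND,+,+,ND,ND
Papaver atlanticum,+,ND,ND,ND,ND,ND,ND,ND
Papaver californicum,+,ND,ND,ND,ND,ND,ND,ND
Papaver nudicaule,ND,ND,ND,ND,ND,ND,ND,ND
Papaver pavonium,ND,ND,ND,ND,ND,ND,ND,ND
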