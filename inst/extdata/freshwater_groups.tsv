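Clitellata	Clitellata
Polychaeta	Polychaeta
Coleoptera	Coleoptera
Diptera	Diptera
Ephemeroptera	Ephemeroptera
Megaloptera	Megaloptera
Odonata	Odonata
Plecoptera	Plecoptera
Trichoptera	Trichoptera
Amphipoda	Amphipoda
Isopoda	Isopoda
Bivalvia	Bivalvia
Gastropoda	Gastropoda
Turbellaria	Turbellaria
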