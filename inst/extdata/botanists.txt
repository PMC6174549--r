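# Synthetic fixture dictionary of botanist surnames, one per line.
Humboldt
Bonpland
Steudel
Lehmann
Kirchner
Hartmann
Siebold
Zuccarini
Ledebour
Trautvetter
Fenzl
Boissier
Grisebach
Ascherson
Engler
Diels
Pilger
Ulbrich
Mattfeld
Schlechter
Radlkofer
Hieronymus
Niedenzu
Loesener
Lindau
Volkens
Koernicke
Guerke
Schumann
Warburg
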