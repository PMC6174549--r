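Berlin	Germany
Grunewald	Germany
Potsdam	Germany
Spandau	Germany
Dahlem	Germany
East Berlin	Germany
Heidelberg	Germany
Freiburg	Germany
Innsbruck	Austria
Salzburg	Austria
Lausanne	Switzerland
Grindelwald	Switzerland
Dolomites	Italy
Toscana	Italy
Provence	France
Pyrenees	France
Andalusia	Spain
Algarve	Portugal
Peloponnese	Greece
Anatolia	Turkey
Caucasus	Georgia
Altai	Russia
Kamchatka	Russia
Hokkaido	Japan
Kyoto	Japan
Yunnan	China
Sikkim	India
Valparaiso	Chile
Bogota	Colombia
Tsavo	Kenya
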