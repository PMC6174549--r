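# Synthetic fixture dictionary of scientific names (binomials), one per line.
Ocimum basilicum
Salvia officinalis
Quercus robur
Fagus sylvatica
Betula pendula
Pinus sylvestris
Abies alba
Picea abies
Larix decidua
Acer platanoides
Fraxinus excelsior
Tilia cordata
Ulmus glabra
Carpinus betulus
Corylus avellana
Sorbus aucuparia
Prunus spinosa
Crataegus monogyna
Rosa canina
Rubus idaeus
Fragaria vesca
Potentilla erecta
Geum urbanum
Trifolium pratense
Vicia cracca
Lathyrus pratensis
Lotus corniculatus
Medicago lupulina
Geranium pratense
Erodium cicutarium
Viola tricolor
Hypericum perforatum
Epilobium angustifolium
Daucus carota
Heracleum sphondylium
Primula veris
Lysimachia vulgaris
Gentiana verna
Myosotis arvensis
Veronica chamaedrys
Plantago lanceolata
Campanula rotundifolia
Achillea millefolium
Leucanthemum vulgare
Centaurea cyanus
Taraxacum officinale
Cichorium intybus
Allium ursinum
Convallaria majalis
Dactylis glomerata
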