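"scientificName","class","phylum","eventDate","year","decimalLatitude","decimalLongitude","locality","institutionCode","catalogNumber"
"Carcinus maenas","Malacostraca","Arthropoda","1905-06-14","","","","Helgoland","ZMK","TOY-001"
"Carcinus maenas","Malacostraca","Arthropoda","1907-07-02","","",""," helgoland ","ZMK","TOY-002"
"Carcinus maenas","Malacostraca","Arthropoda","","1910","54.1","7.9","","ZMK","TOY-003"
"Carcinus maenas","Malacostraca","Arthropoda","","1955","54.5","5.2","","ZMK","TOY-004"
"Carcinus maenas","Malacostraca","Arthropoda","","1980","55.0","4.1","","ZMK","TOY-005"
"Carcinus maenas","Malacostraca","Arthropoda","","2000","54.8","3.9","","ZMK","TOY-006"
"Gibbula cineraria","Gastropoda","Mollusca","","1920","54.2","7.8","","ZMK","TOY-007"
"Gibbula cineraria","Gastropoda","Mollusca","","1950","54.3","7.7","","ZMK","TOY-008"
"Steromphala cineraria","Gastropoda","Mollusca","","1980","54.2","7.6","","ZMK","TOY-009"
"Steromphala cineraria","Gastropoda","Mollusca","","1995","54.1","7.5","","ZMK","TOY-010"
"Asterias rubens","Asteroidea","Echinodermata","","1903","55.2","6.3","","ZMK","TOY-011"
"Asterias rubens","Asteroidea","Echinodermata","","1905","55.2","6.3","","ZMK","TOY-012"
"Asterias rubens","Asteroidea","Echinodermata","","1908","55.2","6.3","","ZMK","TOY-013"
"Asterias rubens","Asteroidea","Echinodermata","","1910","55.2","6.3","","ZMK","TOY-014"
"Asterias rubens","Asteroidea","Echinodermata","","1960","55.2","6.3","","ZMK","TOY-015"
"Asterias rubens","Asteroidea","Echinodermata","","1990","55.2","6.3","","ZMK","TOY-016"
"Mytilus edulis","Bivalvia","Mollusca","","1900","54.7","8.1","","ZMK","TOY-017"
"Mytilus edulis","Bivalvia","Mollusca","","1905","54.7","8.1","","ZMK","TOY-018"
"Mytilus edulis","Bivalvia","Mollusca","","1975","54.7","8.1","","ZMK","TOY-019"
"Mytilus edulis","Bivalvia","Mollusca","","1985","54.7","8.1","","ZMK","TOY-020"
"Mytilus edulis","Bivalvia","Mollusca","","2005","54.7","8.1","","ZMK","TOY-021"
"Crepidula fornicata","Gastropoda","Mollusca","","1934","54.0","7.2","","ZMK","TOY-022"
"Crepidula fornicata","Gastropoda","Mollusca","","1954","54.0","7.2","","ZMK","TOY-023"
"Crepidula fornicata","Gastropoda","Mollusca","","1980","54.0","7.2","","ZMK","TOY-024"
"Crepidula fornicata","Gastropoda","Mollusca","","1992","54.0","7.2","","ZMK","TOY-025"
"Crepidula fornicata","Gastropoda","Mollusca","","2001","54.0","7.2","","ZMK","TOY-026"
"Carcinus maenas","Malacostraca","Arthropoda","","1905","","","unknown bay","ZMK","TOY-027"
"Asterias rubens","Asteroidea","Echinodermata","","1950","","","somewhere","ZMK","TOY-028"
"Mytilus edulis","Bivalvia","Mollusca","","1960","","","","ZMK","TOY-029"
"Carcinus maenas","Malacostraca","Arthropoda","","1970","52.0","20.0","","ZMK","TOY-030"
"Asterias rubens","Asteroidea","Echinodermata","","1971","40.0","5.0","","ZMK","TOY-031"
"Mytilus edulis","Bivalvia","Mollusca","","1972","52.0","-15.0","","ZMK","TOY-032"
"Crepidula fornicata","Gastropoda","Mollusca","","1973","60.0","20.0","","ZMK","TOY-033"
"Asterias rubens","Asteroidea","Echinodermata","no date","","54.5","6.0","","ZMK","TOY-034"
"Asterias rubens","Asteroidea","Echinodermata","no date","","54.5","6.0","","ZMK","TOY-035"
"Asterias rubens","Asteroidea","Echinodermata","no date","","54.5","6.0","","ZMK","TOY-036"
"Asterias rubens","Asteroidea","Echinodermata","no date","","54.5","6.0","","ZMK","TOY-037"
"Asterias rubens","Asteroidea","Echinodermata","no date","","54.5","6.0","","ZMK","TOY-038"
"Nereis pelagica","Polychaeta","Annelida","","1950","54.5","6.5","","ZMK","TOY-039"
"Nereis pelagica","Polychaeta","Annelida","","1950","54.5","6.5","","ZMK","TOY-040"
"Nereis pelagica","Polychaeta","Annelida","","1950","54.5","6.5","","ZMK","TOY-041"
"Nereis pelagica","Polychaeta","Annelida","","1950","54.5","6.5","","ZMK","TOY-042"
"Carcinus sp.","Malacostraca","Arthropoda","","1950","54.5","6.1","","ZMK","TOY-043"
"Mytilus","Bivalvia","Mollusca","","1951","54.5","6.2","","ZMK","TOY-044"
"Asterias indet.","Asteroidea","Echinodermata","","1952","54.5","6.3","","ZMK","TOY-045"
"Mya arenaria","Bivalvia","Mollusca","","1950","54.4","6.4","","ZMK","TOY-046"
"Ensis ensis","Bivalvia","Mollusca","","1955","54.4","6.5","","ZMK","TOY-047"
"Parvicardium minimum","Bivalvia","Mollusca","","1960","54.4","6.6","","ZMK","TOY-048"
"Carcinus maenas","Malacostraca","Arthropoda","","1965","52.0","9.0","","ZMK","TOY-049"
"Asterias rubens","Asteroidea","Echinodermata","","1966","52.5","9.5","","ZMK","TOY-050"
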