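(Branchiostoma_floridae:700,(Ciona_intestinalis:650,(Petromyzon_marinus:615,((Callorhinchus_milii:420,Scyliorhinus_canicula:420)Chondrichthyes:53,((Erpetoichthys_calabaricus:368,(Lepisosteus_oculatus:315,(Danio_rerio:230,Oryzias_latipes:230)Teleostei:85)Neopterygii:53)Actinopterygii:67,(Latimeria_chalumnae:413,(Xenopus_tropicalis:352,(((Anolis_carolinensis:167,Python_bivittatus:167)Squamata:113,(Chrysemys_picta:255,(Gallus_gallus:98,Taeniopygia_guttata:98)Aves:157)Archelosauria:25)Sauropsida:39,(Ornithorhynchus_anatinus:177,(Monodelphis_domestica:159,(Canis_lupus:94,(Homo_sapiens:87,Mus_musculus:87)Euarchontoglires:7)Placentalia:65)Theria:18)Mammalia:142)Amniota:33)Tetrapoda:61)Sarcopterygii:22)Euteleostomi:38)Gnathostomata:142)Vertebrata:35)Olfactores:50)Chordata;
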