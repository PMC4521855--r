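species,common_name,group,status,mass_kg,island_proportion,n,biomass_kg
Cephalophus ogilbyi ogilbyi,Ogilby's Duiker,ungulate,LC,19.50,1.00,9381,182929.50
Philantomba monticola,Blue Duiker,ungulate,LC,4.90,1.00,49318,241658.20
Potamochoerus porcus,Red River Hog,ungulate,LC,80.00,0.00,266,21280.00
Ceratogymna atrata,Black-casqued Hornbill,avian,LC,1.50,1.00,1473,2209.50
Corythaeola cristata,Great Blue Turaco,avian,LC,1.20,1.00,2259,2710.80
Gypohierax angolensis,Palm-nut Vulture,avian,LC,2.00,0.99,391,782.00
Nandinia binotata,African Palm Civet,other,LC,2.95,0.00,1241,3660.95
Poiana richardsonii,African Linsang,other,LC,0.60,0.11,588,352.80
Dendrohyrax dorsalis,Western Tree Hyrax,other,LC,3.00,1.00,1553,4659.00
Manis tricuspis,Tree Pangolin,other,NT,1.50,0.50,6302,9453.00
Smutsia gigantea,Giant Ground Pangolin,other,VU,32.50,0.00,118,3835.00
Allochrocebus preussi insularis,Bioko Preuss's Monkey,primate,EN,4.50,1.00,2142,9639.00
Cercopithecus erythrotis erythrotis,Bioko Red-eared Monkey,primate,VU,3.40,1.00,17997,61189.80
Cercopithecus nictitans martini,Stampfli's Putty-Nosed Monkey,primate,LC,4.60,0.98,336,1545.60
Cercopithecus pogonias pogonias,Golden-bellied Crowned Monkey,primate,LC,3.25,1.00,2720,8840.00
Colobus satanas satanas,Bioko Black Colobus,primate,VU,9.25,1.00,5122,47378.50
Mandrillus leucophaeus poensis,Bioko Drill,primate,EN,14.25,1.00,5004,71307.00
Procolobus pennantii,Pennant's Red Colobus,primate,CR,10.50,1.00,1754,18417.00
Sciurocheirus alleni alleni,Bioko Allen's Galago,primate,LC,0.26,1.00,160,41.60
Kinyxis erosa,Serrated Hinge-back Tortoise,reptile,DD,1.00,0.00,3323,3323.00
Osteolaemus tetraspis,Dwarf Crocodile,reptile,VU,7.50,0.00,1913,14347.50
Python sebae,African Rock Python,reptile,DD,13.83,1.00,1001,13841.41
Varanus niloticus,Nile Monitor,reptile,DD,6.50,0.45,1618,10517.00
Atherurus africanus,African Brush-tailed Porcupine,rodent,LC,2.83,0.91,24302,68798.96
Cricetomys emini,Emin's Pouched Rat,rodent,LC,1.14,1.00,44624,50871.36
Myosciurus pumilio,African Pygmy Squirrel,rodent,LC,0.02,1.00,105,2.10
Protoxerus stangeri,African Giant Squirrel,rodent,LC,0.77,1.00,9967,7674.59
Thryonomys swinderianus,Greater Cane Rat,rodent,LC,6.65,0.00,1914,12728.10
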