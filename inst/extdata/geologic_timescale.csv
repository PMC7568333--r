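stage,older,younger,epoch
Hettangian,201.4,199.4,Early Jurassic
Sinemurian,199.4,192.9,Early Jurassic
Pliensbachian,192.9,184.2,Early Jurassic
Toarcian,184.2,174.7,Early Jurassic
Aalenian,174.7,170.9,Middle Jurassic
Bajocian,170.9,168.2,Middle Jurassic
Bathonian,168.2,165.3,Middle Jurassic
Callovian,165.3,161.5,Middle Jurassic
Oxfordian,161.5,154.8,Late Jurassic
Kimmeridgian,154.8,149.2,Late Jurassic
Tithonian,149.2,145.0,Late Jurassic
Berriasian,145.0,139.8,Early Cretaceous
Valanginian,139.8,132.6,Early Cretaceous
Hauterivian,132.6,125.8,Early Cretaceous
Barremian,125.8,121.4,Early Cretaceous
Aptian,121.4,113.0,Early Cretaceous
Albian,113.0,100.5,Early Cretaceous
Cenomanian,100.5,93.9,Late Cretaceous
Turonian,93.9,89.8,Late Cretaceous
Coniacian,89.8,86.3,Late Cretaceous
Santonian,86.3,83.6,Late Cretaceous
Campanian,83.6,72.1,Late Cretaceous
Maastrichtian,72.1,66.0,Late Cretaceous
Danian,66.0,61.6,Paleocene
Selandian,61.6,59.2,Paleocene
Thanetian,59.2,56.0,Paleocene
Ypresian,56.0,47.8,Eocene
Lutetian,47.8,41.2,Eocene
Bartonian,41.2,37.7,Eocene
Priabonian,37.7,33.9,Eocene
Rupelian,33.9,27.8,Oligocene
Chattian,27.8,23.0,Oligocene
Aquitanian,23.0,20.4,Miocene
Burdigalian,20.4,16.0,Miocene
Langhian,16.0,13.8,Miocene
Serravallian,13.8,11.6,Miocene
Tortonian,11.6,7.2,Miocene
Messinian,7.2,5.3,Miocene
Zanclean,5.3,3.6,Pliocene
Piacenzian,3.6,2.6,Pliocene
Pleistocene,2.6,0.0117,Pleistocene
Recent,0.0117,0,Recent
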