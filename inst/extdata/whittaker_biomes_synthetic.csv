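biome_id,biome,temp_c,precip_cm
1,Tundra,-15,0
1,Tundra,0,0
1,Tundra,0,10
1,Tundra,-7,25
1,Tundra,-15,15
2,Boreal forest,-7,25
2,Boreal forest,0,10
2,Boreal forest,3,15
2,Boreal forest,3,90
2,Boreal forest,-2,60
3,Temperate seasonal forest,3,36
3,Temperate seasonal forest,20,70
3,Temperate seasonal forest,20,220
3,Temperate seasonal forest,3,84
4,Temperate rain forest,6,108
4,Temperate rain forest,20,220
4,Temperate rain forest,20,310
4,Temperate rain forest,6,200
5,Tropical rain forest,20,220
5,Tropical rain forest,30,250
5,Tropical rain forest,30,450
5,Tropical rain forest,20,400
6,Tropical seasonal forest/savanna,25,80
6,Tropical seasonal forest/savanna,30,60
6,Tropical seasonal forest/savanna,30,250
6,Tropical seasonal forest/savanna,20,220
6,Tropical seasonal forest/savanna,20,80
7,Subtropical desert,18,0
7,Subtropical desert,30,0
7,Subtropical desert,30,60
7,Subtropical desert,25,55
8,Temperate grassland/desert,0,0
8,Temperate grassland/desert,18,0
8,Temperate grassland/desert,25,55
8,Temperate grassland/desert,3,15
8,Temperate grassland/desert,0,10
9,Woodland/shrubland,3,15
9,Woodland/shrubland,25,55
9,Woodland/shrubland,25,80
9,Woodland/shrubland,3,36
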