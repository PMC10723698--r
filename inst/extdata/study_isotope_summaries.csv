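category,guild,land_use,d13C_mean,d13C_sd,d15N_mean,d15N_sd,n
biofilm,,forest,-24.8,9.7,-1.1,9.2,28
biofilm,,coffee,-28.2,1.9,2.5,3.0,18
biofilm,,pasture,-26.1,1.5,1.7,2.6,15
leaf_litter,,forest,-32.3,1.9,-1.9,2.2,28
leaf_litter,,coffee,-31.5,2.0,-0.5,2.5,18
leaf_litter,,pasture,-28.5,4.2,-1.9,2.0,15
Tipulidae,detritivore,forest,-27.5,0.7,0.7,1.8,9
Tipulidae,detritivore,coffee,-27.4,1.2,2.4,3.4,2
Tipulidae,detritivore,pasture,-27.4,0.8,0.0,1.4,5
Calamoceratidae,detritivore,forest,-27.5,0.9,2.6,2.1,15
Calamoceratidae,detritivore,coffee,-27.8,1.0,3.2,1.5,3
Calamoceratidae,detritivore,pasture,-28.3,1.2,0.8,1.2,7
Decapoda,detritivore,forest,-26.0,1.4,4.4,3.4,16
Decapoda,detritivore,coffee,-26.9,2.1,5.3,2.5,8
Decapoda,detritivore,pasture,-24.7,3.0,3.3,2.7,8
Tadpole,herbivore,forest,-26.9,2.1,4.6,2.8,21
Tadpole,herbivore,coffee,-27.3,1.5,4.5,2.7,10
Tadpole,herbivore,pasture,-27.7,3.5,4.3,2.0,10
Hydropsychidae,omnivore,forest,-26.4,1.7,3.5,2.8,13
Hydropsychidae,omnivore,coffee,-25.5,2.3,6.3,2.3,5
Hydropsychidae,omnivore,pasture,-26.6,0.9,1.8,2.7,8
Poecilidae,omnivore,forest,-26.1,1.2,6.8,2.1,9
Poecilidae,omnivore,coffee,-26.1,2.2,7.5,2.3,8
Poecilidae,omnivore,pasture,-27.9,1.4,7.4,0.8,2
Libellulidae,carnivore,forest,-25.9,1.8,4.5,2.4,25
Libellulidae,carnivore,coffee,-26.2,1.6,5.7,1.9,11
Libellulidae,carnivore,pasture,-25.6,2.9,3.5,2.1,11
Perlidae,carnivore,forest,-26.5,1.6,4.1,2.4,18
Perlidae,carnivore,coffee,-26.2,1.5,4.7,2.4,9
Perlidae,carnivore,pasture,-24.6,1.8,4.7,2.0,9
Belostomatidae,carnivore,forest,-25.8,1.3,4.0,2.6,16
Belostomatidae,carnivore,coffee,-26.3,1.7,4.6,3.0,10
Belostomatidae,carnivore,pasture,-26.6,3.1,2.9,2.2,7
Megaloptera,carnivore,forest,-26.1,1.3,4.4,2.8,12
Megaloptera,carnivore,coffee,-25.8,1.6,4.4,4.1,9
Megaloptera,carnivore,pasture,-26.1,0.4,3.9,2.9,4
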