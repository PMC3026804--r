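table,column,type,description
visitation,population_id,string,population the record belongs to
visitation,survey,integer,survey round within the season
visitation,plant_id,string,labelled individual plant
visitation,pollinator_species,string,pollinator species id (NA on zero-visit effort placeholder rows)
visitation,functional_group,string,"one of large_bee, small_bee, wasp, beefly, hoverfly, beetle, butterfly, other (NA on placeholders)"
visitation,visits,integer,visits by this species to this plant during this survey (>= 0)
visitation,minutes_observed,real,observation minutes for this plant in this survey (> 0)
visitation,open_flowers,integer,open flowers on the plant during the survey
plants,population_id,string,population the plant belongs to
plants,plant_id,string,plant identifier
plants,x,real,plant x coordinate within the plot (m)
plants,y,real,plant y coordinate within the plot (m)
plants,flowers,integer,flowers displayed over the season (>= 1)
plants,latent_connectivity,real,normalized degree in the realized plant projection (synthetic studies)
plants,so_ratio,real,proportion of ovules setting seed
plants,seeds_per_fruit,integer,seeds per fruit
plants,fruits,integer,ripe fruits produced over the plant's life
plants,seeds,integer,lifetime seed production (fruits x seeds per fruit)
plants,germinants,integer,seedlings emerged from 10 planted seeds
plants,survivors,integer,seedlings surviving to flowering adulthood
plants,juveniles,real,estimated adult offspring (seeds x survivors / seeds planted)
populations,population_id,string,population identifier
populations,x_km,real,population x coordinate (km)
populations,y_km,real,population y coordinate (km)
populations,n_plants,integer,plants marked in the population
populations,pool_richness,integer,pollinator species pool size (synthetic studies)
populations,visit_rate,real,realized per-plant-minute visitation rate (synthetic studies)
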