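species_id,name,distance_class,window_spring_start,window_spring_end,window_autumn_start,window_autumn_end
ficedula_hypoleuca,pied flycatcher,long,91,151,,
sylvia_communis,common whitethroat,long,91,181,,
sylvia_curruca,lesser whitethroat,long,91,181,,
prunella_modularis,dunnock,short,60,151,244,334
phylloscopus_trochilus,willow warbler,long,91,181,182,304
erithacus_rubecula,robin,short,91,151,244,334
phoenicurus_phoenicurus,redstart,long,91,181,182,304
turdus_philomelos,song thrush,short,91,151,213,273
troglodytes_troglodytes,wren,short,,,244,334
regulus_regulus,goldcrest,short,,,244,334
acrocephalus_scirpaceus,reed warbler,long,,,213,304
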