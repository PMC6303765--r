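species_id,season,years_to_recovery,count
ficedula_hypoleuca,spring,2,14
ficedula_hypoleuca,spring,3,3
ficedula_hypoleuca,spring,4,3
ficedula_hypoleuca,spring,5,1
ficedula_hypoleuca,spring,6,1
sylvia_communis,spring,2,7
sylvia_communis,spring,3,2
sylvia_communis,spring,4,2
sylvia_curruca,spring,2,10
sylvia_curruca,spring,3,3
sylvia_curruca,spring,4,2
sylvia_curruca,spring,5,0
sylvia_curruca,spring,6,1
prunella_modularis,spring,2,24
prunella_modularis,spring,3,5
prunella_modularis,spring,4,5
prunella_modularis,spring,5,0
prunella_modularis,spring,6,0
prunella_modularis,spring,7,3
prunella_modularis,spring,8,0
prunella_modularis,spring,9,1
phylloscopus_trochilus,spring,2,34
phylloscopus_trochilus,spring,3,13
phylloscopus_trochilus,spring,4,3
phylloscopus_trochilus,spring,5,0
phylloscopus_trochilus,spring,6,2
erithacus_rubecula,spring,2,42
erithacus_rubecula,spring,3,19
erithacus_rubecula,spring,4,8
erithacus_rubecula,spring,5,1
erithacus_rubecula,spring,6,1
erithacus_rubecula,spring,7,2
erithacus_rubecula,spring,8,1
phoenicurus_phoenicurus,spring,2,19
phoenicurus_phoenicurus,spring,3,8
phoenicurus_phoenicurus,spring,4,1
turdus_philomelos,spring,2,41
turdus_philomelos,spring,3,25
turdus_philomelos,spring,4,7
turdus_philomelos,spring,5,3
turdus_philomelos,spring,6,2
turdus_philomelos,spring,7,3
turdus_philomelos,spring,8,1
turdus_philomelos,spring,9,1
prunella_modularis,autumn,2,16
prunella_modularis,autumn,3,4
prunella_modularis,autumn,4,6
prunella_modularis,autumn,5,0
prunella_modularis,autumn,6,2
phylloscopus_trochilus,autumn,2,4
phylloscopus_trochilus,autumn,3,0
phylloscopus_trochilus,autumn,4,2
phylloscopus_trochilus,autumn,5,2
erithacus_rubecula,autumn,2,53
erithacus_rubecula,autumn,3,17
erithacus_rubecula,autumn,4,5
erithacus_rubecula,autumn,5,0
erithacus_rubecula,autumn,6,1
erithacus_rubecula,autumn,7,1
phoenicurus_phoenicurus,autumn,2,4
phoenicurus_phoenicurus,autumn,3,5
phoenicurus_phoenicurus,autumn,4,2
phoenicurus_phoenicurus,autumn,5,1
turdus_philomelos,autumn,2,84
turdus_philomelos,autumn,3,35
turdus_philomelos,autumn,4,16
turdus_philomelos,autumn,5,6
turdus_philomelos,autumn,6,3
turdus_philomelos,autumn,7,1
troglodytes_troglodytes,autumn,2,10
troglodytes_troglodytes,autumn,3,1
regulus_regulus,autumn,2,3
regulus_regulus,autumn,3,1
regulus_regulus,autumn,4,1
acrocephalus_scirpaceus,autumn,2,4
acrocephalus_scirpaceus,autumn,3,3
acrocephalus_scirpaceus,autumn,4,4
acrocephalus_scirpaceus,autumn,5,0
acrocephalus_scirpaceus,autumn,6,0
acrocephalus_scirpaceus,autumn,7,1
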