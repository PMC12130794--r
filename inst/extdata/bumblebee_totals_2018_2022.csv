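bee_species,total
B. friseanus,5048
B. lepidus,3172
B. festivus,1607
B. impetuosus,477
B. securus,131
B. minshanicola,78
B. nobilis,48
B. prshewalskyi,13
B. graham,7
B. avanus,6
B. hengduanensis,6
B. remotus,3
B. infrequens,1
B. turneri,1
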