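parent1,parent2,cross,weight
Cocker Spaniel,Poodle,Cockerpoo,4.1
Labrador Retriever,Poodle,Labradoodle,2.5
Cavalier King Charles Spaniel,Poodle,Cavapoo,1.1
Cocker Spaniel,English Springer Spaniel,Sprocker,1.0
Bichon Frise,Cavalier King Charles Spaniel,Cavachon,0.5
Golden Retriever,Poodle,Goldendoodle,0.5
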