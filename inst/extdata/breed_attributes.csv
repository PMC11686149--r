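breed,size,cephalic,weight
Labrador Retriever,large,mesocephalic,10.2
Cocker Spaniel,medium,mesocephalic,6.9
Staffordshire Bull Terrier,medium,mesocephalic,4.7
English Springer Spaniel,medium,mesocephalic,4.3
German Shepherd,large,dolichocephalic,3.5
French Bulldog,small,brachycephalic,3.4
Golden Retriever,large,mesocephalic,2.7
Pug,small,brachycephalic,2.7
Border Terrier,small,mesocephalic,2.5
Shih Tzu,small,brachycephalic,2.4
Cavalier King Charles Spaniel,small,brachycephalic,2.4
Jack Russell Terrier,small,mesocephalic,2.4
Bulldog,medium,brachycephalic,2.4
West Highland White Terrier,small,mesocephalic,2.1
Boxer,large,brachycephalic,2.1
Miniature Schnauzer,small,mesocephalic,1.8
Yorkshire Terrier,small,mesocephalic,1.8
Border Collie,medium,dolichocephalic,1.7
Chihuahua Smooth Coat,small,brachycephalic,1.6
Poodle,unclassified,mesocephalic,1.5
Rottweiler,large,mesocephalic,1.4
Lhasa Apso,small,brachycephalic,1.2
Bichon Frise,small,mesocephalic,1.1
Chihuahua Long Coat,small,brachycephalic,1.1
Siberian Husky,large,mesocephalic,1.0
Dachshund Miniature Smooth Haired,small,dolichocephalic,1.0
Beagle,medium,mesocephalic,1.0
Pomeranian,small,mesocephalic,0.9
Dobermann,large,dolichocephalic,0.9
Dogue de Bordeaux,large,brachycephalic,0.9
Dachshund Smooth Haired,small,dolichocephalic,0.8
Greyhound,large,dolichocephalic,0.8
Whippet,medium,dolichocephalic,0.8
Shar Pei,medium,brachycephalic,0.6
Dachshund Miniature Long Haired,small,dolichocephalic,0.5
Great Dane,large,mesocephalic,0.5
Bull Terrier,medium,mesocephalic,0.5
Shetland Sheepdog,small,dolichocephalic,0.4
Rough Collie,large,dolichocephalic,0.4
Basset Hound,medium,mesocephalic,0.4
English Setter,large,mesocephalic,0.3
Bernese Mountain Dog,large,mesocephalic,0.3
Weimaraner,large,dolichocephalic,0.3
Airedale Terrier,large,mesocephalic,0.2
Papillon,small,mesocephalic,0.2
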