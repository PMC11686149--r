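alias,breed
Labrador,Labrador Retriever
Labrador Retreiver,Labrador Retriever
Alsatian,German Shepherd
German Shepherd Dog,German Shepherd
Westie,West Highland White Terrier
West Highland Terrier,West Highland White Terrier
Staffy,Staffordshire Bull Terrier
Staffie,Staffordshire Bull Terrier
Staffordshire Terrier,Staffordshire Bull Terrier
Jack Russell,Jack Russell Terrier
Jack Russel Terrier,Jack Russell Terrier
Frenchie,French Bulldog
English Bulldog,Bulldog
British Bulldog,Bulldog
Yorkie,Yorkshire Terrier
Sausage Dog,Dachshund Smooth Haired
Mini Schnauzer,Miniature Schnauzer
Schnauzer Miniature,Miniature Schnauzer
Springer Spaniel,English Springer Spaniel
Collie,Border Collie
Cavalier King Charles,Cavalier King Charles Spaniel
King Charles Cavalier,Cavalier King Charles Spaniel
Husky,Siberian Husky
Chihuahua,Chihuahua Smooth Coat
Dachshund,Dachshund Smooth Haired
Miniature Dachshund,Dachshund Miniature Smooth Haired
Doberman,Dobermann
Doberman Pinscher,Dobermann
Golden Retreiver,Golden Retriever
Sharpei,Shar Pei
Bichon,Bichon Frise
Pomeranion,Pomeranian
Sheltie,Shetland Sheepdog
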