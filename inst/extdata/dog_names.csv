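name
Alfie
Archie
Bailey
Barney
Bella
Belle
Benji
Bertie
Biscuit
Bonnie
Bramble
Bruno
Buddy
Buster
Buttons
Casper
Charlie
Chester
Chip
Cleo
Coco
Cooper
Daisy
Dexter
Diesel
Digby
Dolly
Dotty
Duke
Dylan
Ella
Ellie
Elsa
Evie
Finn
Fletcher
Florence
Frankie
Freddie
Freya
George
Gracie
Gus
Harley
Harry
Hazel
Henry
Holly
Honey
Hugo
Humphrey
Jack
Jasper
Jess
Jet
Juno
Kiki
Lady
Leo
Lexi
Lily
Lola
Louie
Lucky
Luna
Mabel
Maggie
Marley
Max
Meg
Merlin
Mia
Millie
Milo
Minnie
Mister
Molly
Monty
Murphy
Nala
Nellie
Nero
Noodle
Oakley
Ollie
Oscar
Otis
Otto
Patch
Peanut
Pebbles
Penny
Pepper
Percy
Pip
Piper
Poppy
Prince
Pudding
Ralph
Rex
Riley
Rocky
Rolo
Rosie
Roxy
Ruby
Rufus
Rusty
Sadie
Sam
Sasha
Scout
Shadow
Sky
Smudge
Sooty
Sparky
Spot
Stanley
Storm
Sunny
Tally
Teddy
Tilly
Toby
Truffle
Twiggy
Vinnie
Waffle
Wilbur
Willow
Winston
Woody
Ziggy
Zorro
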