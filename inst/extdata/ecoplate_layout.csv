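well,substrate,category,replicate
A1,CONTROL,control,1
B1,Pyruvic Acid Methyl Ester,carboxylic,1
C1,Tween 40,polymers,1
D1,Tween 80,polymers,1
E1,alpha-Cyclodextrin,polymers,1
F1,Glycogen,polymers,1
G1,D-Cellobiose,carbohydrates,1
H1,alpha-D-Lactose,carbohydrates,1
A2,beta-Methyl-D-Glucoside,carbohydrates,1
B2,D-Xylose,carbohydrates,1
C2,i-Erythritol,carbohydrates,1
D2,D-Mannitol,carbohydrates,1
E2,N-Acetyl-D-Glucosamine,carbohydrates,1
F2,D-Glucosaminic Acid,carboxylic,1
G2,Glucose-1-Phosphate,carbohydrates,1
H2,DL-alpha-Glycerol Phosphate,carbohydrates,1
A3,D-Galactonic Acid gamma-Lactone,carbohydrates,1
B3,D-Galacturonic Acid,carboxylic,1
C3,2-Hydroxy Benzoic Acid,phenolic,1
D3,4-Hydroxy Benzoic Acid,phenolic,1
E3,gamma-Hydroxybutyric Acid,carboxylic,1
F3,Itaconic Acid,carboxylic,1
G3,alpha-Ketobutyric Acid,carboxylic,1
H3,D-Malic Acid,carboxylic,1
A4,L-Arginine,amino_acids,1
B4,L-Asparagine,amino_acids,1
C4,L-Phenylalanine,amino_acids,1
D4,L-Serine,amino_acids,1
E4,L-Threonine,amino_acids,1
F4,Glycyl-L-Glutamic Acid,amino_acids,1
G4,Phenylethylamine,amines,1
H4,Putrescine,amines,1
A5,CONTROL,control,2
B5,Pyruvic Acid Methyl Ester,carboxylic,2
C5,Tween 40,polymers,2
D5,Tween 80,polymers,2
E5,alpha-Cyclodextrin,polymers,2
F5,Glycogen,polymers,2
G5,D-Cellobiose,carbohydrates,2
H5,alpha-D-Lactose,carbohydrates,2
A6,beta-Methyl-D-Glucoside,carbohydrates,2
B6,D-Xylose,carbohydrates,2
C6,i-Erythritol,carbohydrates,2
D6,D-Mannitol,carbohydrates,2
E6,N-Acetyl-D-Glucosamine,carbohydrates,2
F6,D-Glucosaminic Acid,carboxylic,2
G6,Glucose-1-Phosphate,carbohydrates,2
H6,DL-alpha-Glycerol Phosphate,carbohydrates,2
A7,D-Galactonic Acid gamma-Lactone,carbohydrates,2
B7,D-Galacturonic Acid,carboxylic,2
C7,2-Hydroxy Benzoic Acid,phenolic,2
D7,4-Hydroxy Benzoic Acid,phenolic,2
E7,gamma-Hydroxybutyric Acid,carboxylic,2
F7,Itaconic Acid,carboxylic,2
G7,alpha-Ketobutyric Acid,carboxylic,2
H7,D-Malic Acid,carboxylic,2
A8,L-Arginine,amino_acids,2
B8,L-Asparagine,amino_acids,2
C8,L-Phenylalanine,amino_acids,2
D8,L-Serine,amino_acids,2
E8,L-Threonine,amino_acids,2
F8,Glycyl-L-Glutamic Acid,amino_acids,2
G8,Phenylethylamine,amines,2
H8,Putrescine,amines,2
A9,CONTROL,control,3
B9,Pyruvic Acid Methyl Ester,carboxylic,3
C9,Tween 40,polymers,3
D9,Tween 80,polymers,3
E9,alpha-Cyclodextrin,polymers,3
F9,Glycogen,polymers,3
G9,D-Cellobiose,carbohydrates,3
H9,alpha-D-Lactose,carbohydrates,3
A10,beta-Methyl-D-Glucoside,carbohydrates,3
B10,D-Xylose,carbohydrates,3
C10,i-Erythritol,carbohydrates,3
D10,D-Mannitol,carbohydrates,3
E10,N-Acetyl-D-Glucosamine,carbohydrates,3
F10,D-Glucosaminic Acid,carboxylic,3
G10,Glucose-1-Phosphate,carbohydrates,3
H10,DL-alpha-Glycerol Phosphate,carbohydrates,3
A11,D-Galactonic Acid gamma-Lactone,carbohydrates,3
B11,D-Galacturonic Acid,carboxylic,3
C11,2-Hydroxy Benzoic Acid,phenolic,3
D11,4-Hydroxy Benzoic Acid,phenolic,3
E11,gamma-Hydroxybutyric Acid,carboxylic,3
F11,Itaconic Acid,carboxylic,3
G11,alpha-Ketobutyric Acid,carboxylic,3
H11,D-Malic Acid,carboxylic,3
A12,L-Arginine,amino_acids,3
B12,L-Asparagine,amino_acids,3
C12,L-Phenylalanine,amino_acids,3
D12,L-Serine,amino_acids,3
E12,L-Threonine,amino_acids,3
F12,Glycyl-L-Glutamic Acid,amino_acids,3
G12,Phenylethylamine,amines,3
H12,Putrescine,amines,3
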