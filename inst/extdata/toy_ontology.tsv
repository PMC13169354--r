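id	level1	level2	smarts
Amide_NSub	Carbonyl	Amide	[CX3](=O)[NX3]
Ester_Alk	Carbonyl	Ester	[CX3](=O)[OX2][#6]
Acid_Carboxylic	Carbonyl	Acid	[CX3](=O)[OX2H]
Ketone_Dialkyl	Carbonyl	Ketone	[#6][CX3](=O)[#6]
Aldehyde_Any	Carbonyl	Aldehyde	[CX3H1]=O
Sulfonamide_Prim	Sulfur	Sulfonamide	[SX4](=O)(=O)[NX3]
Sulfone_Any	Sulfur	Sulfone	[SX4](=O)(=O)([#6])[#6]
Thioether_Dialkyl	Sulfur	Thioether	[#6X4][SX2][#6]
Nitro_Any	Nitrogen	Nitro	[NX3+](=O)[O-]
Nitrile_Any	Nitrogen	Nitrile	[CX2]#[NX1]
Amine_Prim	Nitrogen	Amine	[NX3H2][#6]
Amine_Tert	Nitrogen	Amine	[NX3]([CX4])([CX4])[#6]
Imine_CN	Nitrogen	Imine	[CX3]=[NX2]
Ether_Dialkyl	Oxygen	Ether	[#6][OX2][#6]
Alcohol_Alkyl	Oxygen	Alcohol	[OX2H][CX4]
Phenol_OH	Oxygen	Phenol	[OX2H]c
X-Cl_Ar	Halogen	ArylHalide	Clc
X-F_Ar	Halogen	ArylHalide	Fc
X-Br_Ar	Halogen	ArylHalide	Brc
X-Hal_Alk	Halogen	AlkylHalide	[CX4][F,Cl,Br,I]
Enone_Michael	Alert	MichaelAcceptor	[CX3]=[CX3][CX3]=[OX1]
Ring_Pyridine	Heteroaromatic	Azine	n1ccccc1
Azole_NH	Heteroaromatic	Azole	[nH]
Ring_Thiophene	Heteroaromatic	Thiophene	c1ccsc1
Ring_Furan	Heteroaromatic	Furan	c1ccoc1
Ring_Benzene	Aromatic	Benzene	c1ccccc1
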