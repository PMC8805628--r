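phoneme	class	plosive	fricative	affricate	nasal	approximant	bilabial	labiodental	dental	alveolar	postalveolar	velar	glottal	voiced	unvoiced	high	low	front	back	diphthong
P	consonant	1	0	0	0	0	1	0	0	0	0	0	0	0	1	0	0	0	0	0
B	consonant	1	0	0	0	0	1	0	0	0	0	0	0	1	0	0	0	0	0	0
T	consonant	1	0	0	0	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0
D	consonant	1	0	0	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0	0
K	consonant	1	0	0	0	0	0	0	0	0	0	1	0	0	1	0	0	0	0	0
G	consonant	1	0	0	0	0	0	0	0	0	0	1	0	1	0	0	0	0	0	0
F	consonant	0	1	0	0	0	0	1	0	0	0	0	0	0	1	0	0	0	0	0
V	consonant	0	1	0	0	0	0	1	0	0	0	0	0	1	0	0	0	0	0	0
TH	consonant	0	1	0	0	0	0	0	1	0	0	0	0	0	1	0	0	0	0	0
DH	consonant	0	1	0	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0	0
S	consonant	0	1	0	0	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0
Z	consonant	0	1	0	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0	0
SH	consonant	0	1	0	0	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0
ZH	consonant	0	1	0	0	0	0	0	0	0	1	0	0	1	0	0	0	0	0	0
HH	consonant	0	1	0	0	0	0	0	0	0	0	0	1	0	1	0	0	0	0	0
CH	consonant	0	0	1	0	0	0	0	0	0	1	0	0	0	1	0	0	0	0	0
JH	consonant	0	0	1	0	0	0	0	0	0	1	0	0	1	0	0	0	0	0	0
M	consonant	0	0	0	1	0	1	0	0	0	0	0	0	1	0	0	0	0	0	0
N	consonant	0	0	0	1	0	0	0	0	1	0	0	0	1	0	0	0	0	0	0
NG	consonant	0	0	0	1	0	0	0	0	0	0	1	0	1	0	0	0	0	0	0
L	consonant	0	0	0	0	1	0	0	0	1	0	0	0	1	0	0	0	0	0	0
R	consonant	0	0	0	0	1	0	0	0	1	0	0	0	1	0	0	0	0	0	0
W	consonant	0	0	0	0	1	1	0	0	0	0	1	0	1	0	0	0	0	0	0
Y	consonant	0	0	0	0	1	0	0	0	0	1	0	0	1	0	0	0	0	0	0
IY	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	1	0	0
IH	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	1	0	0
EH	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	1	0	0
AE	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	1	0	0
AH	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	0	0
AA	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	1	0
AO	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	1	0
UH	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	0	1	0
UW	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	0	1	0
ER	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0
EY	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	1	0	1
AY	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	1	0	1
OY	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	1	1
AW	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	1	1
OW	vowel	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	1	1
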