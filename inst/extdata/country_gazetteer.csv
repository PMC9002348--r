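iso3,variant,canonical
USA,United States of America,1
USA,United States,0
USA,USA,0
USA,US,0
USA,U.S.A,0
CAN,Canada,1
AUS,Australia,1
GBR,United Kingdom,1
GBR,UK,0
GBR,England,0
GBR,Scotland,0
GBR,Wales,0
GBR,Northern Ireland,0
BRA,Brazil,1
BRA,Brasil,0
CHE,Switzerland,1
COL,Colombia,1
LBN,Lebanon,1
DEU,Germany,1
SWE,Sweden,1
FRA,France,1
NOR,Norway,1
THA,Thailand,1
IND,India,1
NLD,Netherlands,1
NLD,The Netherlands,0
ESP,Spain,1
DNK,Denmark,1
PHL,Philippines,1
ARG,Argentina,1
CHL,Chile,1
CHN,China,1
CHN,People's Republic of China,0
CUB,Cuba,1
ETH,Ethiopia,1
IRL,Ireland,1
ITA,Italy,1
JAM,Jamaica,1
KEN,Kenya,1
MWI,Malawi,1
MEX,Mexico,1
MEX,México,0
NPL,Nepal,1
PER,Peru,1
EGY,Egypt,1
SAU,Saudi Arabia,1
BEL,Belgium,1
TCD,Chad,1
ECU,Ecuador,1
FIN,Finland,1
IRN,Iran,1
ISR,Israel,1
MLT,Malta,1
POL,Poland,1
PRT,Portugal,1
SWZ,Eswatini,1
SWZ,Swaziland,0
NGA,Nigeria,1
PAK,Pakistan,1
RWA,Rwanda,1
AUT,Austria,1
CRI,Costa Rica,1
GRC,Greece,1
JOR,Jordan,1
ROU,Romania,1
TZA,Tanzania,1
BGD,Bangladesh,1
BWA,Botswana,1
BGR,Bulgaria,1
COG,Congo,1
GMB,Gambia,1
IDN,Indonesia,1
JPN,Japan,1
KAZ,Kazakhstan,1
LSO,Lesotho,1
MKD,North Macedonia,1
MKD,Macedonia,0
MYS,Malaysia,1
MMR,Myanmar,1
PRI,Puerto Rico,1
SGP,Singapore,1
SDN,Sudan,1
TUR,Turkey,1
UGA,Uganda,1
ZAF,South Africa,1
NZL,New Zealand,1
KOR,South Korea,1
KOR,Republic of Korea,0
RUS,Russia,1
RUS,Russian Federation,0
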