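protein_a	protein_b	ppi_id
act1	abp1	DIP-10439E
app1	abp1	DIP-9959E
cla4	abp1	DIP-3499E
sla1	abp1	DIP-2452E
srv2	abp1	DIP-1139E
yor284w	abp1	DIP-3500E
act1	act1	DIP-1145E
bni1	act1	DIP-1155E
cof1	act1	DIP-1157E
las17	act1	DIP-1158E
pfy1	act1	DIP-1143E
sla2	act1	DIP-1175E
act1	aip1	DIP-1140E
srv2	aip1	DIP-3502E
hsl7	app1	DIP-3683E
rvs167	app1	DIP-3907E
sla2	app1	DIP-3966E
ysc84	app1	DIP-11282E
cdc42	bni1	DIP-1154E
cap2	cap1	DIP-3546E
gic2	cap1	DIP-3547E
cla4	cdc42	DIP-2580E
gic2	cdc42	DIP-2583E
gic2	cla4	DIP-3639E
aip1	cof1	DIP-1346E
app1	cof1	DIP-14613E
las17	cof1	DIP-1161E
app1	crn1	DIP-3604E
cof1	crn1	DIP-11816E
crn1	crn1	DIP-4127E
hsl7	hsl7	DIP-9812E
swe1	hsl7	DIP-7787E
cap2	las17	DIP-1160E
las17	las17	DIP-11092E
rvs167	las17	DIP-3699E
sla1	las17	DIP-1162E
sla2	las17	DIP-15438E
ysc84	las17	DIP-11095E
bni1	pfy1	DIP-1164E
bnr1	pfy1	DIP-1166E
srv2	pfy1	DIP-3762E
app1	rvs161	DIP-4047E
las17	rvs161	DIP-4048E
ybr108w	rvs161	DIP-1781E
abp1	rvs167	DIP-1138E
acf2	rvs167	DIP-3900E
act1	rvs167	DIP-1146E
rvs161	rvs167	DIP-1780E
rvs167	rvs167	DIP-3901E
sla2	rvs167	DIP-10013E
ybr108w	rvs167	DIP-3902E
ygr268c	rvs167	DIP-3903E
yjr083c	rvs167	DIP-3904E
ypr171w	rvs167	DIP-10016E
ysc84	rvs167	DIP-10017E
app1	sla1	DIP-10020E
rvs167	sla1	DIP-10011E
srv2	sla1	DIP-10018E
ygr268c	sla1	DIP-10019E
yor284w	sla1	DIP-11232E
ypr171w	sla1	DIP-3964E
abp1	sla2	DIP-2453E
cla4	sla2	DIP-3965E
sla2	sla2	DIP-3144E
act1	srv2	DIP-1144E
cof1	srv2	DIP-11822E
rvs167	srv2	DIP-3029E
srv2	srv2	DIP-1177E
trm5	srv2	DIP-4014E
crn1	svl3	DIP-3603E
app1	swe1	DIP-4050E
ygr268c	ygr268c	DIP-2272E
ysc84	ygr268c	DIP-2243E
las17	yhr133c	DIP-3700E
yjr083c	yjr083c	DIP-4186E
ysc84	yjr083c	DIP-11280E
rvs167	ynl086w	DIP-3906E
rvs167	yor284w	DIP-10015E
sla2	yor284w	DIP-3967E
yor284w	yor284w	DIP-6160E
ysc84	yor284w	DIP-11283E
las17	ypl246c	DIP-3702E
sla1	ypl246c	DIP-11231E
cap1	ypr171w	DIP-9981E
ysc84	ypr171w	DIP-11285E
abp1	ysc84	DIP-11370E
acf2	ysc84	DIP-11277E
sla1	ysc84	DIP-2242E
sla2	ysc84	DIP-3968E
ypl246c	ysc84	DIP-11284E
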