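DIP-1160E
DIP-3604E
DIP-10439E
DIP-9959E
DIP-2452E
DIP-1139E
DIP-3500E
DIP-1145E
DIP-1155E
DIP-1157E
DIP-1158E
DIP-1143E
DIP-1175E
DIP-1140E
DIP-3502E
DIP-3683E
DIP-3907E
DIP-3966E
DIP-11282E
DIP-1154E
DIP-3546E
DIP-3547E
DIP-2580E
DIP-2583E
DIP-3639E
DIP-1346E
DIP-14613E
DIP-1161E
DIP-11816E
DIP-4127E
DIP-9812E
DIP-7787E
DIP-11092E
DIP-3699E
DIP-1162E
DIP-15438E
DIP-11095E
DIP-1164E
DIP-1166E
DIP-3762E
DIP-4047E
DIP-4048E
DIP-1781E
DIP-1138E
DIP-3900E
DIP-1146E
DIP-1780E
DIP-3901E
DIP-10013E
DIP-3902E
DIP-3903E
DIP-3904E
DIP-10016E
DIP-10017E
DIP-10020E
DIP-10011E
DIP-10018E
DIP-10019E
DIP-11232E
DIP-3964E
DIP-2453E
DIP-3965E
DIP-3144E
DIP-1144E
DIP-11822E
DIP-3029E
DIP-1177E
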