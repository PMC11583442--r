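sample_id,gene_0001,gene_0002,gene_0003,gene_0004,gene_0005,gene_0006,gene_0007,gene_0008,gene_0009,gene_0010,gene_0011,gene_0012,gene_0013,gene_0014,gene_0015,gene_0016,gene_0017,gene_0018,gene_0019,gene_0020,gene_0021,gene_0022,gene_0023,gene_0024,gene_0025,gene_0026,gene_0027,gene_0028,gene_0029,gene_0030,gene_0031,gene_0032,gene_0033,gene_0034,gene_0035,gene_0036,gene_0037,gene_0038,gene_0039,gene_0040
sample_001,57,161,184,108,361,41,164,73,72,308,89,276,51,117,90,56,59,98,412,63,206,47,63,94,88,157,129,163,48,155,82,109,82,82,58,196,198,126,39,110
sample_002,40,57,99,137,72,44,64,145,127,27,153,101,139,296,137,36,54,38,55,207,44,28,70,34,311,120,114,110,74,86,42,47,145,156,123,195,48,238,177,188
sample_003,25,140,76,165,21,389,62,157,18,173,49,93,128,49,135,157,104,99,180,92,215,137,45,177,68,190,65,95,66,43,120,27,113,158,42,16,87,134,90,152
sample_004,88,68,140,124,122,64,89,98,159,84,35,78,77,54,73,62,84,75,59,234,54,190,61,68,117,427,88,96,282,6,113,71,190,127,42,121,31,70,55,246
sample_005,56,35,84,37,33,220,90,170,221,25,160,48,315,136,249,341,50,195,97,79,87,58,74,118,95,22,30,32,86,194,131,65,51,51,247,42,80,47,189,79
sample_006,64,337,248,71,27,46,133,106,30,95,257,116,60,167,36,15,62,18,82,11,177,96,260,37,65,79,83,62,180,96,236,115,60,261,108,59,432,165,102,132
sample_007,90,244,113,46,26,483,17,50,58,38,88,130,121,75,202,758,51,45,125,102,23,46,60,140,108,66,70,306,96,102,74,58,79,40,204,58,57,105,28,231
sample_008,40,204,23,113,550,68,145,61,39,119,29,83,82,202,33,85,159,87,8,131,96,156,209,88,142,344,42,96,150,102,97,55,23,110,196,144,498,65,102,528
sample_009,261,109,92,182,15,120,76,111,319,94,92,22,103,82,612,234,21,141,63,73,139,33,26,166,92,35,52,56,67,52,73,62,120,17,66,32,69,349,129,34
sample_010,64,56,96,86,93,57,77,122,82,112,195,123,106,118,101,91,218,29,59,54,93,49,325,59,110,150,192,156,493,79,54,68,173,137,77,356,37,261,90,98
sample_011,36,79,47,21,31,226,56,87,92,69,60,77,103,8,60,86,50,41,71,45,165,121,59,201,75,25,29,113,42,109,47,22,91,26,232,31,68,138,30,131
sample_012,124,60,82,100,69,123,72,241,54,650,123,207,196,22,53,23,279,416,65,43,50,233,151,94,128,114,36,88,40,73,214,30,222,89,157,195,105,71,76,51
sample_013,82,41,373,80,269,145,31,121,90,135,302,210,14,63,49,111,27,92,119,68,84,197,118,223,65,87,189,63,68,48,65,77,81,47,130,86,103,121,124,12
sample_014,60,112,57,107,114,134,291,32,50,57,106,74,35,28,82,214,135,109,167,59,236,176,419,172,403,579,44,140,25,76,110,129,65,130,253,41,36,120,113,117
sample_015,196,19,23,144,60,70,72,81,41,187,109,13,176,87,16,197,6,260,79,104,159,125,24,122,155,38,31,55,14,68,206,102,280,120,51,92,138,75,69,68
sample_016,100,123,46,15,97,10,62,77,51,49,221,42,92,46,66,97,67,20,150,104,58,181,246,333,290,151,59,112,238,80,88,98,244,74,135,111,47,85,44,32
sample_017,71,117,125,74,226,131,108,109,535,58,218,428,261,262,32,518,14,130,278,151,75,144,131,36,41,88,498,109,166,50,193,144,91,80,32,41,165,57,136,183
sample_018,19,187,80,30,106,14,111,73,89,47,71,68,183,34,165,27,521,20,77,73,281,179,302,37,178,963,151,162,66,187,107,36,223,205,78,59,86,50,161,127
sample_019,132,70,140,235,109,188,141,185,236,21,87,131,178,34,210,52,11,35,38,430,78,49,74,166,198,54,67,32,31,54,54,116,68,95,61,92,148,136,81,259
sample_020,141,162,136,343,143,19,40,224,92,37,158,56,49,27,357,30,173,125,161,336,292,153,141,188,163,89,221,142,790,86,147,129,257,133,47,130,78,159,124,51
sample_021,203,68,61,87,107,173,143,104,21,143,133,48,242,84,130,199,43,69,59,86,105,20,67,83,284,29,20,125,41,300,54,36,121,28,96,113,85,74,113,151
sample_022,108,88,124,38,99,77,298,28,43,138,95,36,68,96,111,19,239,43,94,144,116,156,98,69,131,88,61,186,132,98,90,45,116,39,110,44,162,110,62,110
sample_023,115,52,59,27,130,193,126,65,79,62,45,12,23,169,99,165,40,126,142,35,155,48,69,80,26,98,242,99,75,323,108,64,90,170,86,16,105,149,42,62
sample_024,116,100,141,129,22,43,135,31,44,22,23,127,110,111,140,41,120,211,86,85,121,116,160,168,38,211,28,92,87,131,103,30,91,42,112,37,122,47,30,116
sample_025,188,101,94,319,8,316,486,209,282,42,76,143,166,84,116,13,47,44,109,96,201,200,97,71,65,85,14,66,102,208,109,70,116,228,63,146,140,97,24,221
sample_026,212,86,68,92,230,33,37,25,221,178,57,226,156,18,184,54,355,142,109,194,134,104,63,241,29,142,111,114,136,54,104,96,82,58,157,113,24,143,181,234
sample_027,252,133,100,270,147,132,168,100,43,21,239,190,106,61,131,73,11,194,17,46,68,151,24,89,87,44,70,303,74,62,171,124,91,35,83,258,114,98,34,44
sample_028,46,43,87,53,35,25,71,138,98,54,233,34,56,166,138,50,259,87,305,104,83,36,185,190,126,117,43,158,316,52,289,71,132,258,210,64,32,163,52,251
sample_029,32,111,115,176,30,291,160,26,54,93,120,136,68,83,27,344,20,117,406,64,180,218,34,45,23,56,110,10,24,79,59,190,384,93,11,148,94,9,154,140
sample_030,115,85,36,79,62,54,154,213,132,54,83,125,54,67,84,59,135,54,42,182,72,24,97,180,261,208,67,19,40,141,40,69,67,107,40,24,54,37,88,243
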