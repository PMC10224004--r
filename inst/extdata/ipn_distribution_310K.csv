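system,solute,cd_name,cd_conc_M,D,sd
octanol,IPN,,0,2.651,0.093
octanol,INZ,,0,0.633,0.021
octanol,iNAM,,0,0.446,0.013
hexane,IPN,,0,0.00124,0.0000191
hexane,INZ,,0,0.0008254,0.0000188
hexane,iNAM,,0,0.0005742,0.0000172
octanol,IPN,HP-b-CD,0.0115,2.413,0.086
octanol,IPN,HP-b-CD,0.025,2.138,0.087
octanol,IPN,HP-b-CD,0.035,1.922,0.096
octanol,IPN,M-b-CD,0.0115,2.558,0.081
octanol,IPN,M-b-CD,0.025,2.459,0.068
octanol,IPN,M-b-CD,0.035,2.363,0.072
hexane,IPN,HP-b-CD,0.0115,0.0009138,0.0000161
hexane,IPN,HP-b-CD,0.025,0.0004311,0.0000113
hexane,IPN,HP-b-CD,0.035,0.0001672,0.0000061
hexane,IPN,M-b-CD,0.0115,0.00102,0.000021
hexane,IPN,M-b-CD,0.025,0.0006763,0.0000122
hexane,IPN,M-b-CD,0.035,0.0005525,0.0000128
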