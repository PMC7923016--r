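breed,n,locus,allele,freq
Mora Romagnola,342,MC1R,E+,0.192
Mora Romagnola,342,MC1R,e,0.809
Mora Romagnola,342,MC1R,ED1,0.000
Mora Romagnola,342,MC1R,ED2,0.000
Mora Romagnola,342,MC1R,EP,0.000
Mora Romagnola,342,NR6A1,T,1.000
Mora Romagnola,342,NR6A1,C,0.000
Apulo Calabrese,101,MC1R,E+,0.040
Apulo Calabrese,101,MC1R,e,0.035
Apulo Calabrese,101,MC1R,ED1,0.000
Apulo Calabrese,101,MC1R,ED2,0.856
Apulo Calabrese,101,MC1R,EP,0.069
Apulo Calabrese,101,NR6A1,T,0.856
Apulo Calabrese,101,NR6A1,C,0.144
Casertana,161,MC1R,E+,0.124
Casertana,161,MC1R,e,0.019
Casertana,161,MC1R,ED1,0.000
Casertana,161,MC1R,ED2,0.767
Casertana,161,MC1R,EP,0.090
Casertana,161,NR6A1,T,0.938
Casertana,161,NR6A1,C,0.062
Cinta Senese,122,MC1R,E+,0.004
Cinta Senese,122,MC1R,e,0.041
Cinta Senese,122,MC1R,ED1,0.004
Cinta Senese,122,MC1R,ED2,0.820
Cinta Senese,122,MC1R,EP,0.131
Cinta Senese,122,NR6A1,T,1.000
Cinta Senese,122,NR6A1,C,0.000
Nero Siciliano,108,MC1R,E+,0.120
Nero Siciliano,108,MC1R,e,0.005
Nero Siciliano,108,MC1R,ED1,0.056
Nero Siciliano,108,MC1R,ED2,0.630
Nero Siciliano,108,MC1R,EP,0.190
Nero Siciliano,108,NR6A1,T,0.718
Nero Siciliano,108,NR6A1,C,0.282
Sarda,58,MC1R,E+,0.302
Sarda,58,MC1R,e,0.060
Sarda,58,MC1R,ED1,0.060
Sarda,58,MC1R,ED2,0.578
Sarda,58,MC1R,EP,0.000
Sarda,58,NR6A1,T,0.991
Sarda,58,NR6A1,C,0.009
Wild Boar,113,MC1R,E+,0.925
Wild Boar,113,MC1R,e,0.022
Wild Boar,113,MC1R,ED1,0.000
Wild Boar,113,MC1R,ED2,0.004
Wild Boar,113,MC1R,EP,0.049
Wild Boar,113,NR6A1,T,0.018
Wild Boar,113,NR6A1,C,0.982
Italian Large White,49,MC1R,E+,0.000
Italian Large White,49,MC1R,e,0.000
Italian Large White,49,MC1R,ED1,0.000
Italian Large White,49,MC1R,ED2,0.000
Italian Large White,49,MC1R,EP,1.000
Italian Large White,49,NR6A1,T,1.000
Italian Large White,49,NR6A1,C,0.000
Italian Landrace,44,MC1R,E+,0.000
Italian Landrace,44,MC1R,e,0.000
Italian Landrace,44,MC1R,ED1,0.000
Italian Landrace,44,MC1R,ED2,0.000
Italian Landrace,44,MC1R,EP,1.000
Italian Landrace,44,NR6A1,T,1.000
Italian Landrace,44,NR6A1,C,0.000
Italian Duroc,30,MC1R,E+,0.000
Italian Duroc,30,MC1R,e,1.000
Italian Duroc,30,MC1R,ED1,0.000
Italian Duroc,30,MC1R,ED2,0.000
Italian Duroc,30,MC1R,EP,0.000
Italian Duroc,30,NR6A1,T,1.000
Italian Duroc,30,NR6A1,C,0.000
Pietrain,26,MC1R,E+,0.000
Pietrain,26,MC1R,e,0.000
Pietrain,26,MC1R,ED1,0.000
Pietrain,26,MC1R,ED2,0.000
Pietrain,26,MC1R,EP,1.000
Pietrain,26,NR6A1,T,1.000
Pietrain,26,NR6A1,C,0.000
Belgian Landrace,31,MC1R,E+,0.000
Belgian Landrace,31,MC1R,e,0.000
Belgian Landrace,31,MC1R,ED1,0.000
Belgian Landrace,31,MC1R,ED2,0.000
Belgian Landrace,31,MC1R,EP,1.000
Belgian Landrace,31,NR6A1,T,1.000
Belgian Landrace,31,NR6A1,C,0.000
Hampshire,18,MC1R,E+,0.000
Hampshire,18,MC1R,e,0.000
Hampshire,18,MC1R,ED1,0.000
Hampshire,18,MC1R,ED2,1.000
Hampshire,18,MC1R,EP,0.000
Hampshire,18,NR6A1,T,1.000
Hampshire,18,NR6A1,C,0.000
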