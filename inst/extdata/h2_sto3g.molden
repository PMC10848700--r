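[Molden Format]
[Title]
h2_sto3g RHF/STO-3G (densiwit fixture)
[Atoms] AU
H    1   1       0.0000000000       0.0000000000       0.0000000000
H    2   1       0.0000000000       0.0000000000       1.4010429488
[GTO]
1 0
 s   3 1.00
      3.4252509100E+00     1.5432897070E-01
      6.2391373000E-01     5.3532814244E-01
      1.6885540000E-01     4.4463454203E-01

2 0
 s   3 1.00
      3.4252509100E+00     1.5432897070E-01
      6.2391373000E-01     5.3532814244E-01
      1.6885540000E-01     4.4463454203E-01

[MO]
 Sym= A
 Ene=  -5.7797480720E-01
 Spin= Alpha
 Occup= 2.00000000
    1  -5.4899377719E-01
    2  -5.4899377719E-01
 Sym= A
 Ene=   6.6969866940E-01
 Spin= Alpha
 Occup= 0.00000000
    1  -1.2108225730E+00
    2   1.2108225730E+00
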