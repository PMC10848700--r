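[Molden Format]
[Title]
lih_sto3g RHF/STO-3G (densiwit fixture)
[Atoms] AU
Li   1   3       0.0000000000       0.0000000000       0.0000000000
H    2   1       0.0000000000       0.0000000000       3.0139241961
[GTO]
1 0
 s   3 1.00
      1.6119575000E+01     1.5432897035E-01
      2.9362007000E+00     5.3532814121E-01
      7.9465050000E-01     4.4463454100E-01
 s   3 1.00
      6.3628970000E-01    -9.9967229805E-02
      1.4786010000E-01     3.9951282922E-01
      4.8088700000E-02     7.0011546863E-01
 p   3 1.00
      6.3628970000E-01     1.5591626504E-01
      1.4786010000E-01     6.0768370066E-01
      4.8088700000E-02     3.9195737752E-01

2 0
 s   3 1.00
      3.4252509100E+00     1.5432897070E-01
      6.2391373000E-01     5.3532814244E-01
      1.6885540000E-01     4.4463454203E-01

[MO]
 Sym= A
 Ene=  -2.3486441786E+00
 Spin= Alpha
 Occup= 2.00000000
    1  -9.9124539149E-01
    2  -3.2678102658E-02
    3   0.0000000000E+00
    4   0.0000000000E+00
    5   6.3470892801E-03
    6  -4.4702892240E-03
 Sym= A
 Ene=  -2.8570473702E-01
 Spin= Alpha
 Occup= 2.00000000
    1  -1.6742350597E-01
    2   4.5479321041E-01
    3   0.0000000000E+00
    4   0.0000000000E+00
    5   3.4619995101E-01
    6   5.4878057282E-01
 Sym= A
 Ene=   7.8261848580E-02
 Spin= Alpha
 Occup= 0.00000000
    1  -2.0997752532E-01
    2   7.9961717142E-01
    3   0.0000000000E+00
    4   0.0000000000E+00
    5  -6.1213826536E-01
    6  -1.3979332566E-01
 Sym= A
 Ene=   1.6393842630E-01
 Spin= Alpha
 Occup= 0.00000000
    1   0.0000000000E+00
    2   0.0000000000E+00
    3  -6.6888652296E-01
    4   7.4336452660E-01
    5   0.0000000000E+00
    6   0.0000000000E+00
 Sym= A
 Ene=   1.6393842630E-01
 Spin= Alpha
 Occup= 0.00000000
    1   0.0000000000E+00
    2   0.0000000000E+00
    3   7.4336452660E-01
    4   6.6888652296E-01
    5   0.0000000000E+00
    6   0.0000000000E+00
 Sym= A
 Ene=   5.4912927965E-01
 Spin= Alpha
 Occup= 0.00000000
    1  -9.2838288209E-02
    2   7.0472486741E-01
    3   0.0000000000E+00
    4   0.0000000000E+00
    5   9.8100081963E-01
    6  -1.1873743887E+00
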