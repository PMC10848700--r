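[Molden Format]
[Title]
li2_sto3g RHF/STO-3G (densiwit fixture)
[Atoms] AU
Li   1   3       0.0000000000       0.0000000000       0.0000000000
Li   2   3       0.0000000000       0.0000000000       5.0510489584
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

[MO]
 Sym= A
 Ene=  -2.3300979841E+00
 Spin= Alpha
 Occup= 2.00000000
    1  -7.0040701953E-01
    2  -3.7450990402E-02
    3   0.0000000000E+00
    4   0.0000000000E+00
    5  -8.1990463347E-03
    6   7.0040701954E-01
    7   3.7450990402E-02
    8   0.0000000000E+00
    9   0.0000000000E+00
   10  -8.1990463346E-03
 Sym= A
 Ene=  -2.3300778998E+00
 Spin= Alpha
 Occup= 2.00000000
    1  -7.0091367960E-01
    2  -2.0252264281E-02
    3   0.0000000000E+00
    4   0.0000000000E+00
    5   1.5588798369E-03
    6  -7.0091367959E-01
    7  -2.0252264280E-02
    8   0.0000000000E+00
    9   0.0000000000E+00
   10  -1.5588798370E-03
 Sym= A
 Ene=  -1.4944184231E-01
 Spin= Alpha
 Occup= 2.00000000
    1   1.9803384046E-01
    2  -5.6720287292E-01
    3   0.0000000000E+00
    4   0.0000000000E+00
    5  -1.0162421566E-01
    6   1.9803384046E-01
    7  -5.6720287292E-01
    8   0.0000000000E+00
    9   0.0000000000E+00
   10   1.0162421566E-01
 Sym= A
 Ene=   8.2793099189E-02
 Spin= Alpha
 Occup= 0.00000000
    1  -1.7924882459E-01
    2   7.0084464559E-01
    3   0.0000000000E+00
    4   0.0000000000E+00
    5  -3.0624519089E-01
    6   1.7924882459E-01
    7  -7.0084464559E-01
    8   0.0000000000E+00
    9   0.0000000000E+00
   10  -3.0624519089E-01
 Sym= A
 Ene=   1.3371370271E-01
 Spin= Alpha
 Occup= 0.00000000
    1   0.0000000000E+00
    2   0.0000000000E+00
    3   5.9166326519E-01
    4  -2.0063035691E-01
    5   0.0000000000E+00
    6   0.0000000000E+00
    7   0.0000000000E+00
    8   5.9166326519E-01
    9  -2.0063035691E-01
   10   0.0000000000E+00
 Sym= A
 Ene=   1.3371370271E-01
 Spin= Alpha
 Occup= 0.00000000
    1   0.0000000000E+00
    2   0.0000000000E+00
    3  -2.0063035691E-01
    4  -5.9166326519E-01
    5   0.0000000000E+00
    6   0.0000000000E+00
    7   0.0000000000E+00
    8  -2.0063035691E-01
    9  -5.9166326519E-01
   10   0.0000000000E+00
 Sym= A
 Ene=   1.5764977897E-01
 Spin= Alpha
 Occup= 0.00000000
    1   3.4420692845E-02
    2  -2.9086043291E-01
    3   0.0000000000E+00
    4   0.0000000000E+00
    5   6.4190464524E-01
    6   3.4420692845E-02
    7  -2.9086043291E-01
    8   0.0000000000E+00
    9   0.0000000000E+00
   10  -6.4190464524E-01
 Sym= A
 Ene=   2.4049319505E-01
 Spin= Alpha
 Occup= 0.00000000
    1   0.0000000000E+00
    2   0.0000000000E+00
    3   8.2690083126E-01
    4   1.0794435017E-01
    5   0.0000000000E+00
    6   0.0000000000E+00
    7   0.0000000000E+00
    8  -8.2690083126E-01
    9  -1.0794435017E-01
   10   0.0000000000E+00
 Sym= A
 Ene=   2.4049319505E-01
 Spin= Alpha
 Occup= 0.00000000
    1   0.0000000000E+00
    2   0.0000000000E+00
    3   1.0794435017E-01
    4  -8.2690083126E-01
    5   0.0000000000E+00
    6   0.0000000000E+00
    7   0.0000000000E+00
    8  -1.0794435017E-01
    9   8.2690083126E-01
   10   0.0000000000E+00
 Sym= A
 Ene=   4.6856432163E-01
 Spin= Alpha
 Occup= 0.00000000
    1  -1.3689075529E-01
    2   1.2334775827E+00
    3   0.0000000000E+00
    4   0.0000000000E+00
    5   1.2046673332E+00
    6   1.3689075529E-01
    7  -1.2334775827E+00
    8   0.0000000000E+00
    9   0.0000000000E+00
   10   1.2046673332E+00
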