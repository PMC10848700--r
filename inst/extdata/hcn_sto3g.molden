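[Molden Format]
[Title]
hcn_sto3g RHF/STO-3G (densiwit fixture)
[Atoms] AU
H    1   1       0.0000000000       0.0000000000      -2.0106685966
C    2   6       0.0000000000       0.0000000000       0.0000000000
N    3   7       0.0000000000       0.0000000000       2.1845234000
[GTO]
1 0
 s   3 1.00
      3.4252509100E+00     1.5432897070E-01
      6.2391373000E-01     5.3532814244E-01
      1.6885540000E-01     4.4463454203E-01

2 0
 s   3 1.00
      7.1616837000E+01     1.5432897019E-01
      1.3045096300E+01     5.3532814064E-01
      3.5305122000E+00     4.4463454053E-01
 s   3 1.00
      2.9412494000E+00    -9.9967230076E-02
      6.8348310000E-01     3.9951283030E-01
      2.2228990000E-01     7.0011547053E-01
 p   3 1.00
      2.9412494000E+00     1.5591627211E-01
      6.8348310000E-01     6.0768372820E-01
      2.2228990000E-01     3.9195739529E-01

3 0
 s   3 1.00
      9.9106169000E+01     1.5432897033E-01
      1.8052312000E+01     5.3532814114E-01
      4.8856602000E+00     4.4463454094E-01
 s   3 1.00
      3.7804559000E+00    -9.9967228444E-02
      8.7849660000E-01     3.9951282378E-01
      2.8571440000E-01     7.0011545910E-01
 p   3 1.00
      3.7804559000E+00     1.5591626854E-01
      8.7849660000E-01     6.0768371429E-01
      2.8571440000E-01     3.9195738632E-01

[MO]
 Sym= A
 Ene=  -1.5384832241E+01
 Spin= Alpha
 Occup= 2.00000000
    1   4.7544496093E-04
    2  -4.1419611004E-04
    3   1.0472281118E-02
    4   0.0000000000E+00
    5   0.0000000000E+00
    6   7.6191666324E-03
    7  -9.9397818029E-01
    8  -2.9737700528E-02
    9   0.0000000000E+00
   10   0.0000000000E+00
   11   8.7054695309E-03
 Sym= A
 Ene=  -1.1079621036E+01
 Spin= Alpha
 Occup= 2.00000000
    1   5.9424734587E-03
    2  -9.9289806481E-01
    3  -3.1137282304E-02
    4   0.0000000000E+00
    5   0.0000000000E+00
    6  -1.8474514974E-03
    7   4.9365537605E-04
    8   6.7779835014E-03
    9   0.0000000000E+00
   10   0.0000000000E+00
   11  -1.6555805640E-03
 Sym= A
 Ene=  -1.1803808022E+00
 Spin= Alpha
 Occup= 2.00000000
    1  -6.7223968242E-02
    2   1.6523882379E-01
    3  -3.5698874087E-01
    4   0.0000000000E+00
    5   0.0000000000E+00
    6  -2.0169548711E-01
    7   2.0099835010E-01
    8  -6.2840206383E-01
    9   0.0000000000E+00
   10   0.0000000000E+00
   11   2.2525602930E-01
 Sym= A
 Ene=  -7.5125205323E-01
 Spin= Alpha
 Occup= 2.00000000
    1   4.4924764875E-01
    2  -1.4593390802E-01
    3   4.6534995685E-01
    4   0.0000000000E+00
    5   0.0000000000E+00
    6  -3.9962238299E-01
    7   8.1381915758E-02
    8  -2.8102132196E-01
    9   0.0000000000E+00
   10   0.0000000000E+00
   11  -4.5934810902E-02
 Sym= A
 Ene=  -4.9328527375E-01
 Spin= Alpha
 Occup= 2.00000000
    1   1.5656025230E-01
    2   7.3369014568E-02
    3  -2.1686140360E-01
    4   0.0000000000E+00
    5   0.0000000000E+00
    6  -3.1815211844E-01
    7  -1.3190481421E-01
    8   6.8921943845E-01
    9   0.0000000000E+00
   10   0.0000000000E+00
   11   6.7319223350E-01
 Sym= A
 Ene=  -4.4064857817E-01
 Spin= Alpha
 Occup= 2.00000000
    1   0.0000000000E+00
    2   0.0000000000E+00
    3   0.0000000000E+00
    4  -5.2438006343E-02
    5  -6.1025008478E-01
    6   0.0000000000E+00
    7   0.0000000000E+00
    8   0.0000000000E+00
    9  -5.4374558214E-02
   10  -6.3278681006E-01
   11   0.0000000000E+00
 Sym= A
 Ene=  -4.4064857817E-01
 Spin= Alpha
 Occup= 2.00000000
    1   0.0000000000E+00
    2   0.0000000000E+00
    3   0.0000000000E+00
    4   6.1025008478E-01
    5  -5.2438006343E-02
    6   0.0000000000E+00
    7   0.0000000000E+00
    8   0.0000000000E+00
    9   6.3278681006E-01
   10  -5.4374558214E-02
   11   0.0000000000E+00
 Sym= A
 Ene=   3.4774943769E-01
 Spin= Alpha
 Occup= 0.00000000
    1   0.0000000000E+00
    2   0.0000000000E+00
    3   0.0000000000E+00
    4  -5.3579940518E-01
    5  -6.5264011294E-01
    6   0.0000000000E+00
    7   0.0000000000E+00
    8   0.0000000000E+00
    9   5.2508907886E-01
   10   6.3959420712E-01
   11   0.0000000000E+00
 Sym= A
 Ene=   3.4774943769E-01
 Spin= Alpha
 Occup= 0.00000000
    1   0.0000000000E+00
    2   0.0000000000E+00
    3   0.0000000000E+00
    4   6.5264011294E-01
    5  -5.3579940518E-01
    6   0.0000000000E+00
    7   0.0000000000E+00
    8   0.0000000000E+00
    9  -6.3959420712E-01
   10   5.2508907886E-01
   11   0.0000000000E+00
 Sym= A
 Ene=   5.4860910891E-01
 Spin= Alpha
 Occup= 0.00000000
    1   1.1543325506E+00
    2   1.9111250396E-01
    3  -1.2947763681E+00
    4   0.0000000000E+00
    5   0.0000000000E+00
    6   3.3705526565E-01
    7  -6.0515397804E-02
    8   3.8073560027E-01
    9   0.0000000000E+00
   10   0.0000000000E+00
   11  -4.8098274613E-01
 Sym= A
 Ene=   1.3078648235E+00
 Spin= Alpha
 Occup= 0.00000000
    1   6.5935350347E-01
    2  -6.9447499795E-02
    3   7.7287215452E-01
    4   0.0000000000E+00
    5   0.0000000000E+00
    6   1.5398563094E+00
    7   1.2212311638E-01
    8  -1.2370463696E+00
    9   0.0000000000E+00
   10   0.0000000000E+00
   11   1.0773161361E+00
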