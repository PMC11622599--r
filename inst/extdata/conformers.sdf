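benzene
     RDKit          3D

  6  6  0  0  0  0  0  0  0  0999 V2000
    1.0417    0.8854   -0.0207 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2694   -0.4751   -0.0074 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2367   -1.3932    0.0135 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0479   -0.9029    0.0209 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2705    0.4548    0.0077 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2371    1.3854   -0.0134 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  1  1  0
M  END
$$$$
pyridine
     RDKit          3D

  6  6  0  0  0  0  0  0  0  0999 V2000
   -0.3417    1.1266    0.0370 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2704    0.0894    0.0114 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8543   -1.2218   -0.0318 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4715   -1.5351   -0.0505 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.3987   -0.5318   -0.0259 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0015    0.8036    0.0179 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  1  1  0
M  END
$$$$
furan
     RDKit          3D

  5  5  0  0  0  0  0  0  0  0999 V2000
    0.7025    0.7343   -0.0524 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6937    0.6834   -0.0145 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0672   -0.6359    0.1445 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0436   -1.3678    0.2024 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.0921   -0.5847    0.0890 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  1  0
  5  1  2  0
M  END
$$$$
cyclohexane
     RDKit          3D

  6  6  0  0  0  0  0  0  0  0999 V2000
   -0.7110    1.0488   -0.6629 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6647    1.2765   -0.0428 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4094   -0.0487   -0.1412 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6674   -1.0402    0.7487 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6431   -1.2852    0.0018 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4230    0.0100    0.1957 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  1  1  0
M  END
$$$$
toluene
     RDKit          3D

  7  7  0  0  0  0  0  0  0  0999 V2000
   -2.1895   -0.0720    0.0223 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7006   -0.0256    0.0135 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0107   -1.2044   -0.0719 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3911   -1.1179   -0.0771 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0710    0.0800   -0.0015 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3218    1.2376    0.0828 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0566    1.2092    0.0919 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  2  0
  5  6  1  0
  6  7  2  0
  7  2  1  0
M  END
$$$$
naphthalene
     RDKit          3D

 10 11  0  0  0  0  0  0  0  0999 V2000
    2.2344    1.0685   -0.3566 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5043   -0.2647   -0.0404 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4429   -1.1282    0.2165 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1525   -0.6417    0.1513 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9101   -1.4842    0.4030 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2279   -1.0780    0.3587 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5147    0.2549    0.0432 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4558    1.1036   -0.2099 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1469    0.6689   -0.1582 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9249    1.5287   -0.4146 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  7  1  0
  7  8  2  0
  8  9  1  0
  9 10  2  0
 10  1  1  0
  9  4  1  0
M  END
$$$$
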