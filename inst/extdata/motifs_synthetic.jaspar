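>ETS1 ETS1
A  [ 97 1 1 1 1 97 97 1 1 1 ]
C  [ 1 97 97 1 1 1 1 1 1 1 ]
G  [ 1 1 1 97 97 1 1 97 1 97 ]
T  [ 1 1 1 1 1 1 1 1 97 1 ]
>FOXD2 FOXD2
A  [ 1 1 1 1 1 97 1 1 1 1 1 ]
C  [ 1 1 1 1 1 1 97 1 1 1 1 ]
G  [ 1 97 1 1 1 1 1 1 1 1 97 ]
T  [ 97 1 97 97 97 1 1 97 97 97 1 ]
>HOXB2 HOXB2
A  [ 1 1 97 1 1 97 97 1 1 1 ]
C  [ 1 1 1 1 1 1 1 1 1 1 ]
G  [ 1 97 1 1 1 1 1 1 97 97 ]
T  [ 97 1 1 97 97 1 1 97 1 1 ]
>SOX10 SOX10
A  [ 97 97 1 97 97 1 1 1 1 ]
C  [ 1 1 97 1 1 1 1 1 97 ]
G  [ 1 1 1 1 1 1 97 97 1 ]
T  [ 1 1 1 1 1 97 1 1 1 ]
>YY1 YY1
A  [ 1 1 1 1 1 1 97 1 1 1 1 ]
C  [ 1 97 97 1 97 97 1 1 1 1 1 ]
G  [ 97 1 1 97 1 1 1 1 1 1 1 ]
T  [ 1 1 1 1 1 1 1 97 97 97 97 ]
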