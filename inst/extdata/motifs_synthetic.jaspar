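>SYN0001.1 bcd
A  [ 12  2  0 28  0  1  3 ]
C  [  6  1  0  0  2 25  4 ]
G  [  5  3 28  0  1  2 20 ]
T  [  5 22  0  0 25  0  1 ]
>SYN0002.1 cad
A  [  2 24  0  1 22  3 ]
C  [  3  2  1 25  2  4 ]
G  [ 20  1  2  1  2 16 ]
T  [  3  1 25  1  2  5 ]
>SYN0003.1 dl
A  [  1  0 26  2  1  4  2 ]
C  [ 22  2  0 24  1  3  3 ]
G  [  2 24  1  1  2 17  2 ]
T  [  3  2  1  1 24  4 21 ]
>SYN0004.1 vfl
A  [ 24  1  2  0 23  2 ]
C  [  1 23  2  1  2  3 ]
G  [  2  2 22  1  1 20 ]
T  [  1  2  2 26  2  3 ]
>SYN0005.1 hb
A  [  2 26  1  2 24  1  2 ]
C  [ 21  0  2 22  1  2  3 ]
G  [  2  1 23  1  2  3 20 ]
T  [  3  1  2  3  1 22  3 ]
>SYN0006.1 Kr
A  [  1  2 25  1  2 20 ]
C  [ 24  2  1  2  3  3 ]
G  [  1 22  1  2 21  2 ]
T  [  2  2  1 23  2  3 ]
>SYN0007.1 run
A  [ 23  2  1  2  1 24  2 ]
C  [  2 24  1  1  2  1 21 ]
G  [  1  1 25  2  2  1  2 ]
T  [  2  1  1 23 23  2  3 ]
>SYN0008.1 odd
A  [  2  1 24  2 22  3 ]
C  [ 22  2  1  1  2  2 ]
G  [  2 24  1  2  2 21 ]
T  [  2  1  2 23  2  2 ]
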