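0	ND
2	Chr-Pr
3	Chr-A
4	Chr-A
5	Chr-A
6	Chr-Po
7	Chr-R
8	Chr-Po
9	Chr-A
10	Chr-R
11	Chr-O
12	Chr-A
13	Chr-A
14	Chr-R
15	Hc-P
16	Hc-P
17	Hc-H
18	ND
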