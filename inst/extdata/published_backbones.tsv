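tree	topology	steps
ML	(((((Cerato,Chlor),Eud),Magnol),Mono),Out);	777
2	(((Cerato,Chlor),((Mono,Magnol),Eud)),Out);	775
3	(((Cerato,Chlor),((Mono,Eud),Magnol)),Out);	775
4	(((((Cerato,Mono),Eud),Magnol),Chlor),Out);	783
5	((((Cerato,Chlor),(Eud,Magnol)),Mono),Out);	777
6	((((Cerato,Chlor),Magnol),(Mono,Eud)),Out);	776
7	(((Cerato,Eud),((Chlor,Mono),Magnol)),Out);	784
8	(((((Cerato,Chlor),Magnol),Mono),Eud),Out);	776
9	(((((Cerato,Eud),Mono),Chlor),Magnol),Out);	787
10	((((Cerato,Eud),Mono),(Chlor,Magnol)),Out);	785
11	(((((Cerato,Eud),Magnol),Chlor),Mono),Out);	787
12	(((Cerato,Mono),(Chlor,(Eud,Magnol))),Out);	783
13	(((((Cerato,Eud),Magnol),Mono),Chlor),Out);	784
14	((((Cerato,Mono),Chlor),(Eud,Magnol)),Out);	782
15	(((Cerato,(Mono,Eud)),(Chlor,Magnol)),Out);	782
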