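#NEXUS
[ synthetic example matrix: 6 taxa, 8 multistate characters ]
BEGIN DATA;
  DIMENSIONS NTAX=6 NCHAR=8;
  FORMAT SYMBOLS="012" MISSING=? GAP=-;
  MATRIX
    Amborella   00010210
    Nymphaea    0001?210
    Chloranthus 01110(01)10
    Ceratophyl  0111?100
    Eudicot_sp  1212-100
    Monocot_sp  12120100
  ;
END;

BEGIN ASSUMPTIONS;
  TYPESET * default = ord: 2 4-5, unord: 1 3 6-8;
END;
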