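#NEXUS
BEGIN DATA;
DIMENSIONS NTAX=12 NCHAR=60;
FORMAT MISSING=? GAP=- SYMBOLS="01";
MATRIX
t05  101011010011110000110001111000110101001110100100101011011110
t09  001001000001010100101001101000011101001100000100111001010111
t04  100100001000011011101010110011110011000000101011110011111110
t12  100001011010000100101001111011111011000011000100100011110111
t08  111001100001010110111101110111011100110111010101001001011010
t11  111001100110010010111111010100110100111101111001001011011010
t02  101001000010010010111010110010111101111110101111001001011010
t07  010001001010010010111100101011110001011011001110011000101111
t10  010011001101010110111000111011011001110011000110111100101011
t03  000101101010111010111000111110011101010100001100101000001111
t06  111101101000010001101000011000000101001100010110111001111010
t01  101011111001011001101000001000101101001110001100111011101010
;
END;
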