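>PPH13_SYN synthetic Pph13-like Q50 homeodomain matrix (stand-in, argmax TAATTG)
A [ -1.0  2.0  2.0 -1.0 -1.0  1.0 ]
C [ -1.0 -1.0 -1.0 -1.0 -1.0 -1.0 ]
G [ -0.5 -1.0 -1.0 -1.0 -0.5  2.0 ]
T [  2.0 -1.0 -1.0  2.0  2.0 -1.0 ]
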