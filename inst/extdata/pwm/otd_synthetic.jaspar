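>OTD_SYN synthetic Otd-like K50 homeodomain matrix (stand-in, argmax TAATCC)
A [ -1.0  2.0  2.0 -1.0 -0.5 -1.0 ]
C [ -1.0 -1.0 -1.0 -1.0  2.0  2.0 ]
G [ -0.5 -1.0 -1.0 -1.0  0.5 -0.5 ]
T [  2.0 -1.0 -1.0  2.0 -1.0 -0.5 ]
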