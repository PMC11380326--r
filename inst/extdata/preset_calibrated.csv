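item_id,p_y,p_l,p_u,p_h
A1a,0.835,,,
A1b,0.262,,,
A2a,0.811,,,
A2b,0.050,,,
A3a,0.152,,,
A3b,0.080,,,
A6a,0.012,,,
A6b,0.080,,,
A7a,0.239,,,
A7b,0.123,,,
A9a,0.159,,,
A9b,0.000,,,
A9c,0.006,,,
A9d,0.050,,,
A11,0.060,,,
A12a,1.000,,,
A12b,0.744,,,
A13,0.988,,,
A14,0.646,,,
A15,0.128,,,
A16a,0.050,,,
A16b,0.104,,,
A16c,0.050,,,
A17a,0.982,,,
A17b,0.293,,,
A18,0.860,,,
A20,0.050,,,
A21a,0.348,,,
A21b,0.090,,,
C1a,0.070,,,
C3a,0.122,,,
C3b,0.000,,,
C4b,0.920,,,
C7b,0.000,,,
C8b,0.080,,,
C10,0.050,,,
C12b,0.070,,,
C15,0.262,,,
S1,,0.019,0.971,0.010
S2,,0.085,0.720,0.195
S3,,0.020,0.950,0.030
S4,,0.000,1.000,0.000
S5,,0.134,0.846,0.020
S6,,0.003,0.994,0.003
S7,,0.116,0.874,0.010
S8,,0.060,0.890,0.050
S9,,0.010,0.014,0.976
S10,,0.010,0.892,0.098
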