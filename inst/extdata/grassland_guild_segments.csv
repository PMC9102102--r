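treatment,guild,segment,mean,se
V2,AA,intensification,0.98,0.05
V3,AA,intensification,1.23,0.15
V4,AA,intensification,1.01,0.06
V5,AA,intensification,0.65,0.15
V2,AA,narrowing,0.15,0.09
V3,AA,narrowing,0.24,0.09
V4,AA,narrowing,0.49,0.06
V5,AA,narrowing,0.71,0.12
V2,AA,expansion,0.77,0.23
V3,AA,expansion,0.91,0.24
V4,AA,expansion,0.79,0.26
V5,AA,expansion,0.38,0.30
V2,AA,contraction,0.01,0.01
V3,AA,contraction,0.55,0.31
V4,AA,contraction,0.66,0.24
V5,AA,contraction,0.57,0.12
V2,AM,intensification,0.18,0.07
V3,AM,intensification,0.08,0.03
V4,AM,intensification,0.12,0.08
V5,AM,intensification,0.09,0.05
V2,AM,narrowing,0.22,0.11
V3,AM,narrowing,0.25,0.06
V4,AM,narrowing,0.37,0.07
V5,AM,narrowing,0.24,0.09
V2,AM,expansion,0.10,0.07
V3,AM,expansion,0.11,0.11
V4,AM,expansion,0.07,0.05
V5,AM,expansion,0.10,0.07
V2,AM,contraction,0.00,0.00
V3,AM,contraction,0.17,0.12
V4,AM,contraction,0.92,0.21
V5,AM,contraction,0.26,0.19
V2,CH,intensification,1.23,0.06
V3,CH,intensification,0.94,0.16
V4,CH,intensification,0.60,0.10
V5,CH,intensification,0.91,0.15
V2,CH,narrowing,0.63,0.09
V3,CH,narrowing,1.02,0.14
V4,CH,narrowing,1.36,0.09
V5,CH,narrowing,0.81,0.06
V2,CH,expansion,2.83,0.32
V3,CH,expansion,1.90,0.21
V4,CH,expansion,0.46,0.15
V5,CH,expansion,1.38,0.24
V2,CH,contraction,0.48,0.20
V3,CH,contraction,1.64,0.59
V4,CH,contraction,2.98,0.50
V5,CH,contraction,0.84,0.54
V2,CX,intensification,1.11,0.09
V3,CX,intensification,1.23,0.18
V4,CX,intensification,0.82,0.14
V5,CX,intensification,0.65,0.18
V2,CX,narrowing,0.73,0.17
V3,CX,narrowing,0.87,0.17
V4,CX,narrowing,1.17,0.17
V5,CX,narrowing,1.27,0.15
V2,CX,expansion,1.65,0.16
V3,CX,expansion,1.65,0.38
V4,CX,expansion,1.61,0.40
V5,CX,expansion,0.63,0.20
V2,CX,contraction,0.27,0.22
V3,CX,contraction,0.40,0.13
V4,CX,contraction,2.02,0.75
V5,CX,contraction,1.65,0.44
V2,P,intensification,0.81,0.09
V3,P,intensification,0.44,0.12
V4,P,intensification,0.23,0.08
V5,P,intensification,0.14,0.07
V2,P,narrowing,0.08,0.07
V3,P,narrowing,0.41,0.06
V4,P,narrowing,0.54,0.16
V5,P,narrowing,0.57,0.05
V2,P,expansion,2.11,0.30
V3,P,expansion,1.05,0.41
V4,P,expansion,0.17,0.12
V5,P,expansion,0.62,0.22
V2,P,contraction,0.02,0.02
V3,P,contraction,0.46,0.30
V4,P,contraction,0.67,0.31
V5,P,contraction,0.41,0.17
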