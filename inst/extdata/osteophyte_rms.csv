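specimen,side,region_id,modality_pair,rms_mm
specimen1,medial,o1,CT-SLS,1.30
specimen1,medial,o2,CT-SLS,1.30
specimen1,medial,o3,CT-SLS,1.37
specimen1,medial,o4,CT-SLS,1.03
specimen2,medial,o1,CT-SLS,1.30
specimen2,medial,o2,CT-SLS,1.18
specimen2,medial,o3,CT-SLS,1.20
specimen2,lateral,o1,CT-SLS,0.53
specimen2,lateral,o2,CT-SLS,0.43
specimen2,lateral,o3,CT-SLS,0.42
specimen2,lateral,o4,CT-SLS,0.79
specimen2,lateral,o5,CT-SLS,1.04
specimen3,lateral,o1,CT-SLS,0.63
specimen3,lateral,o2,CT-SLS,0.92
specimen3,lateral,o3,CT-SLS,1.25
specimen3,medial,o1,CT-SLS,0.57
specimen3,medial,o2,CT-SLS,0.82
specimen3,medial,o3,CT-SLS,0.97
specimen1,medial,o1,3DUS-SLS,0.56
specimen1,medial,o2,3DUS-SLS,0.51
specimen1,medial,o3,3DUS-SLS,0.61
specimen1,medial,o4,3DUS-SLS,0.83
specimen2,medial,o1,3DUS-SLS,1.45
specimen2,medial,o2,3DUS-SLS,1.16
specimen2,medial,o3,3DUS-SLS,1.34
specimen2,lateral,o1,3DUS-SLS,0.67
specimen2,lateral,o2,3DUS-SLS,0.88
specimen2,lateral,o3,3DUS-SLS,0.42
specimen2,lateral,o4,3DUS-SLS,0.57
specimen2,lateral,o5,3DUS-SLS,0.75
specimen3,lateral,o1,3DUS-SLS,0.63
specimen3,lateral,o2,3DUS-SLS,1.25
specimen3,lateral,o3,3DUS-SLS,1.48
specimen3,medial,o1,3DUS-SLS,0.94
specimen3,medial,o2,3DUS-SLS,0.75
specimen3,medial,o3,3DUS-SLS,0.88
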