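sl_no,animal_id,ife,are,hre,afp_printed
1,6BA9CA3D-B98E-40DC-B86A-0B2116127746,0.13,-0.05,0.05,0.13
2,6BA9CA3D-B98E-40DC-B86A-0B2116127746,-0.10,-0.05,0.05,-0.11
3,6BA9CA3D-B98E-40DC-B86A-0B2116127746,0.44,-0.05,0.05,0.44
4,6BA9CA3D-B98E-40DC-B86A-0B2116127746,0.49,-0.05,0.05,0.49
5,013CFDC6-0446-471B-AE0D-545834C921AB,-0.33,0.30,0.05,0.03
6,013CFDC6-0446-471B-AE0D-545834C921AB,0.44,0.30,0.05,0.79
7,6BA9CA3D-B98E-40DC-B86A-0B2116127746,0.87,-0.05,0.05,0.87
8,6BA9CA3D-B98E-40DC-B86A-0B2116127746,-0.84,-0.05,0.05,-0.84
9,013CFDC6-0446-471B-AE0D-545834C921AB,-0.30,0.30,0.05,0.05
10,6BA9CA3D-B98E-40DC-B86A-0B2116127746,0.28,-0.05,0.05,0.28
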