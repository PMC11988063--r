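animal_id,gebv
0BB54BC5-F4E4-45C0-903A-A7552588CB13,3.10
1FAA4E0A-75DA-44D5-A94A-A9D7E0252CD6,2.77
3A324D0B-E441-4D59-948D-302CF3FCCCBF,2.44
6ACFB5B6-A14D-403B-9331-8CD0E740439B,2.32
8A3022D7-53F1-4691-A555-EBA1FB5DBC16,2.21
5D127AF5-80CE-4353-B146-401623836E0F,1.63
60AA4C28-B1C4-4AFE-B353-A33327FDE7B0,1.63
87CB327A-C7D6-4DE4-9B99-4E07E94233D5,1.14
2079EDB5-4B26-496E-8CAD-C24F19DB292E,1.11
5A7911D7-F0A6-48D7-9028-1145FE2BCEAE,1.07
6E9BED8F-964B-44FC-AC2C-0CE95A8A12B8,1.05
2996D785-6FD9-42EC-96C0-CF9B59A5E13E,1.05
293DC3D5-9DBE-4C6E-A48E-F645FD5646D8,1.00
7ADB65B4-69AB-4D0C-B460-A0595833BD94,0.97
73BEA21E-6DB6-47FA-A69B-B344797F7126,0.95
405BA838-B753-417D-8B0F-C78D484EF8DF,0.22
82B60872-60DC-450E-A10D-125A87423BB2,0.21
46569474-EF61-40BF-A59C-C66CE550E423,0.13
0D471917-2B6B-4207-90EE-B2655C4FF5DE,0.12
405BA838-B753-417D-8B0F-C78D484EF8DF,0.22
08D7934D-2CBB-44E2-B9C4-85F0E7C9CA84,-0.095
5F8C5E44-918B-4FBF-816F-80B6FC9F1B38,-0.096
2FDCDC60-0FC3-4815-B32C-7DF1A95CF677,-0.096
4AF62135-6568-4262-A994-C82815927CD7,-0.096
1F590D1D-C358-4F6F-B97D-7D580C9D93FD,-0.096
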