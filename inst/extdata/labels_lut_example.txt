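# Example FreeSurfer-style colour lookup table for the 15-class demo map
# id name R G B A
0 background 0 0 0 0
1 cortical_grey 205 62 78 0
2 subcortical_grey 230 148 34 0
3 cerebral_white 245 245 245 0
4 cerebellar_grey 74 155 60 0
5 cerebellar_white 220 248 164 0
6 brainstem 119 159 176 0
7 thalamus 0 118 14 0
8 hippocampus 220 216 20 0
9 amygdala 103 255 255 0
10 ventricle_csf 120 18 134 0
11 external_csf 178 20 60 0
12 choroid_plexus 0 200 200 0
13 vessel 160 32 240 0
14 white_matter_lesion 200 70 255 0
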