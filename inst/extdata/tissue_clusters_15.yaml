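# Default tissue-type clustering for in vivo MRI segmentation: anatomical
# labels grouped into 15 intensity classes so that hundreds of ROIs share a
# handful of Gaussian mixtures. Label ids follow the example LUT shipped
# alongside (labels_lut_example.txt); real atlases supply their own map.
classes:
  - background
  - cortical_grey
  - subcortical_grey
  - cerebral_white
  - cerebellar_grey
  - cerebellar_white
  - brainstem
  - thalamus
  - hippocampus
  - amygdala
  - ventricle_csf
  - external_csf
  - choroid_plexus
  - vessel
  - white_matter_lesion
map:
  "0": 1
  "1": 2
  "2": 3
  "3": 4
  "4": 5
  "5": 6
  "6": 7
  "7": 8
  "8": 9
  "9": 10
  "10": 11
  "11": 12
  "12": 13
  "13": 14
  "14": 15
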