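# Default CTC/tdEV gate library: six tumor classes over four channels.
# CTC = nucleated (DNA+), CD45-, > 4 um, CK and/or HER2 positive with
# marker-DNA overlap; tdEV = anucleate, CD45-, 1-14 um, CK and/or HER2
# positive. Thresholds are calibrated for the synthetic imaging model and
# can be overridden freely.
policy: first_match

class ctc_ck_her2neg
  DNA.mean_int >= 120
  CD45.mean_int < 120
  object.eq_diameter_um > 4
  CK.mean_int >= 150
  HER2.mean_int < 150
  CK.dna_overlap >= 0.5

class ctc_ckneg_her2
  DNA.mean_int >= 120
  CD45.mean_int < 120
  object.eq_diameter_um > 4
  CK.mean_int < 150
  HER2.mean_int >= 150
  HER2.dna_overlap >= 0.5

class ctc_ck_her2
  DNA.mean_int >= 120
  CD45.mean_int < 120
  object.eq_diameter_um > 4
  CK.mean_int >= 150
  HER2.mean_int >= 150
  CK.dna_overlap >= 0.5

class tdev_ck_her2neg
  DNA.mean_int < 120
  CD45.mean_int < 120
  object.eq_diameter_um >= 1
  object.eq_diameter_um <= 14
  CK.mean_int >= 150
  HER2.mean_int < 150

class tdev_ckneg_her2
  DNA.mean_int < 120
  CD45.mean_int < 120
  object.eq_diameter_um >= 1
  object.eq_diameter_um <= 14
  CK.mean_int < 150
  HER2.mean_int >= 150

class tdev_ck_her2
  DNA.mean_int < 120
  CD45.mean_int < 120
  object.eq_diameter_um >= 1
  object.eq_diameter_um <= 14
  CK.mean_int >= 150
  HER2.mean_int >= 150
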