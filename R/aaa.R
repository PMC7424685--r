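# Canonical fluorescence channel names, in fixed order.
EVG_CHANNELS <- c("DNA", "CK", "CD45", "HER2")

# The six tumor classes of the default gate library, CTC before tdEV
# (first-match order), plus the residual label.
EVG_CLASSES <- c("ctc_ck_her2neg", "ctc_ckneg_her2", "ctc_ck_her2",
                 "tdev_ck_her2neg", "tdev_ckneg_her2", "tdev_ck_her2")
EVG_UNCLASSIFIED <- "unclassified"

# Per-channel feature names (10 per channel) plus the "object" pseudo-channel
# carrying union-mask geometry.
EVG_FEATURES <- c("area_um2", "perimeter_um", "eccentricity",
                  "perim_area_ratio", "eq_diameter_um",
                  "mean_int", "max_int", "sd_int", "total_int", "dna_overlap")
EVG_GEOM_FEATURES <- EVG_FEATURES[1:5]
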