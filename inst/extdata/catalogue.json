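{
  "catalogue_version": "1.0",
  "families": {
    "first_order": 19,
    "shape": 16,
    "glcm": 22,
    "glrlm": 16,
    "glszm": 16,
    "gldm": 12,
    "ngtdm": 5
  },
  "features": ["fo_energy", "fo_total_energy", "fo_entropy", "fo_minimum", "fo_p10", "fo_p90", "fo_maximum", "fo_mean", "fo_median", "fo_iqr", "fo_range", "fo_mad", "fo_rmad", "fo_rms", "fo_sd", "fo_variance", "fo_skewness", "fo_kurtosis", "fo_uniformity", "sh_mesh_volume", "sh_voxel_volume", "sh_surface_area", "sh_surface_volume_ratio", "sh_sphericity", "sh_compactness1", "sh_compactness2", "sh_max_3d_diameter", "sh_max_2d_diameter_slice", "sh_max_2d_diameter_column", "sh_max_2d_diameter_row", "sh_major_axis_length", "sh_minor_axis_length", "sh_least_axis_length", "sh_elongation", "sh_flatness", "glcm_autocorrelation", "glcm_joint_average", "glcm_cluster_prominence", "glcm_cluster_shade", "glcm_cluster_tendency", "glcm_contrast", "glcm_correlation", "glcm_difference_average", "glcm_difference_entropy", "glcm_difference_variance", "glcm_joint_energy", "glcm_joint_entropy", "glcm_imc1", "glcm_imc2", "glcm_idm", "glcm_idmn", "glcm_id", "glcm_idn", "glcm_inverse_variance", "glcm_maximum_probability", "glcm_sum_entropy", "glcm_sum_squares", "glrlm_short_run_emphasis", "glrlm_long_run_emphasis", "glrlm_gray_level_nonuniformity", "glrlm_gray_level_nonuniformity_normalized", "glrlm_run_length_nonuniformity", "glrlm_run_length_nonuniformity_normalized", "glrlm_run_percentage", "glrlm_gray_level_variance", "glrlm_run_variance", "glrlm_run_entropy", "glrlm_low_gray_level_run_emphasis", "glrlm_high_gray_level_run_emphasis", "glrlm_short_run_low_gray_level_emphasis", "glrlm_short_run_high_gray_level_emphasis", "glrlm_long_run_low_gray_level_emphasis", "glrlm_long_run_high_gray_level_emphasis", "glszm_small_area_emphasis", "glszm_large_area_emphasis", "glszm_gray_level_nonuniformity", "glszm_gray_level_nonuniformity_normalized", "glszm_size_zone_nonuniformity", "glszm_size_zone_nonuniformity_normalized", "glszm_zone_percentage", "glszm_gray_level_variance", "glszm_zone_variance", "glszm_zone_entropy", "glszm_low_gray_level_zone_emphasis", "glszm_high_gray_level_zone_emphasis", "glszm_small_area_low_gray_level_emphasis", "glszm_small_area_high_gray_level_emphasis", "glszm_large_area_low_gray_level_emphasis", "glszm_large_area_high_gray_level_emphasis", "gldm_small_dependence_emphasis", "gldm_large_dependence_emphasis", "gldm_gray_level_nonuniformity", "gldm_dependence_nonuniformity", "gldm_dependence_nonuniformity_normalized", "gldm_gray_level_variance", "gldm_dependence_variance", "gldm_dependence_entropy", "gldm_low_gray_level_emphasis", "gldm_high_gray_level_emphasis", "gldm_small_dependence_low_gray_level_emphasis", "gldm_large_dependence_high_gray_level_emphasis", "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness", "ngtdm_complexity", "ngtdm_strength"]
}
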