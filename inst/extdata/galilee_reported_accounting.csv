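quantity,numerator,denominator,note
total_res_free,2618,6821,favourable-class areas free of tenure vs total (km2)
habitat_model_free,6703,15563,buffered habitat model free of tenure vs total (km2)
re_10_5_5a_free,501,3030,single-class accounting example (km2)
omission_2dp_refined,2276,2312,recent records inside the 2-dp refined model
omission_3dp_refined,2233,2312,recent records inside the 3-dp refined model
gbos_outside,18104,45258,priority-zone area outside resource tenure (km2)
protected_model,235,15563,national-park coverage of the habitat model (km2)
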