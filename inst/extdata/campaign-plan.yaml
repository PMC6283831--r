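randomize_runs: yes
group1:
  media:
    factors:
    - yeast_extract
    - glycerol
    - tryptone
    - magnesium_sulfate
    - yeast_extract_source
    - ph
    - buffer_capacity
    - osmolality
    p: 3
  microwell:
    factors:
    - well_volume
    - well_fill_volume
    - well_cover
    - well_bottom
    - shake_speed
    p: 0
    na_factors:
    - flask_volume
    - flask_fill_volume
    - flask_cover
    - flask_baffles
  flask:
    factors:
    - flask_volume
    - flask_fill_volume
    - flask_cover
    - flask_baffles
    p: 0
    na_factors:
    - well_volume
    - well_fill_volume
    - well_cover
    - well_bottom
  other:
    factors:
    - growth_time
    - temperature
    - inoculum_amount
    - inoculum_age
    - antibiotic_concentration
    p: 0
    na_factors:
    - flask_volume
    - flask_fill_volume
    - flask_cover
    - flask_baffles
group2:
  large:
    factors:
    - glycerol
    - magnesium_sulfate
    - yeast_extract_source
    - osmolality
    - well_volume
    - well_fill_volume
    - well_cover
    - well_bottom
    - shake_speed
    p: 3
    na_factors:
    - flask_volume
    - flask_fill_volume
    - flask_cover
    - flask_baffles
  small:
    factors:
    - yeast_extract
    - tryptone
    - ph
    - buffer_capacity
    - growth_time
    - temperature
    - inoculum_amount
    - antibiotic_concentration
    p: 3
    na_factors:
    - flask_volume
    - flask_fill_volume
    - flask_cover
    - flask_baffles
group3:
  n_reps: 4
  n_days: 12
  month_split:
  - 7
  - 5
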