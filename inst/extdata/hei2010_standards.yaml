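# Healthy Eating Index 2010 scoring standards.
# All densities are per 1000 kcal. Component maxima sum to 100 points:
# 9 adequacy components (more is better, linear up to the standard) and
# 3 moderation components (less is better, linear between the two bounds).
# Every number here is configuration, not code.
components:
  total_fruit:
    type: adequacy
    max_points: 5
    standard: 0.8          # cup eq/1000 kcal
    field: total_fruit_cup
  whole_fruit:
    type: adequacy
    max_points: 5
    standard: 0.4          # cup eq/1000 kcal
    field: whole_fruit_cup
  total_vegetables:
    type: adequacy
    max_points: 5
    standard: 1.1          # cup eq/1000 kcal
    field: total_veg_cup
  greens_and_beans:
    type: adequacy
    max_points: 5
    standard: 0.2          # cup eq/1000 kcal
    field: greens_beans_cup
  whole_grains:
    type: adequacy
    max_points: 10
    standard: 1.5          # oz eq/1000 kcal
    field: whole_grains_oz
  dairy:
    type: adequacy
    max_points: 10
    standard: 1.3          # cup eq/1000 kcal
    field: dairy_cup
  total_protein:
    type: adequacy
    max_points: 5
    standard: 2.5          # oz eq/1000 kcal
    field: total_protein_oz
  seafood_plant_protein:
    type: adequacy
    max_points: 5
    standard: 0.8          # oz eq/1000 kcal
    field: seafood_plant_oz
  fatty_acids:
    type: ratio            # (MUFA + PUFA) / SFA
    max_points: 10
    max_standard: 2.5      # ratio at/above which max points
    zero_standard: 1.2     # ratio at/below which zero points
    fields: [mufa_g, pufa_g, sat_fat_g]
  refined_grains:
    type: moderation
    max_points: 10
    max_standard: 1.8      # oz eq/1000 kcal, at/below -> max
    zero_standard: 4.3     # oz eq/1000 kcal, at/above -> zero
    field: refined_grains_oz
  sodium:
    type: moderation
    max_points: 10
    max_standard: 1.1      # g/1000 kcal
    zero_standard: 2.0     # g/1000 kcal
    field: sodium_mg
    field_scale: 0.001     # profiles carry sodium in mg
  empty_calories:
    type: empty_calories
    max_points: 20
    max_standard: 19       # percent of energy, at/below -> max
    zero_standard: 50      # percent of energy, at/above -> zero
    fields: [solid_fats_g, added_sugars_tsp, alcohol_g]
energy_conversions:
  solid_fat_kcal_per_g: 9
  added_sugar_kcal_per_tsp: 16
  alcohol_kcal_per_g: 7
alcohol_threshold_g_per_1000kcal: 13
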