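# Default model inputs.
#
# Cure probabilities, pathway probabilities, unit costs (GBP, 2012-13 price
# base) and utilities are the published base-case parameterisations.
# The `accuracy` and `prevalence` sections are SYNTHETIC stand-ins: the
# primary accuracy study's supplementary prevalence/accuracy tables are not
# redistributable, so these are plausible values on the scale of a
# 209-woman cross-sectional cohort, calibrated only so that detrusor
# overactivity is the most prevalent urodynamic finding and the overall
# share of women with a mixed-incontinence history is about 52%. Override
# them with study data where available.
#
# Each parameter entry is one of:
#   {beta: [alpha, beta]}            Beta distribution
#   {gamma: [shape, scale]}          Gamma distribution
#   {dirichlet: {cat: conc, ...}}    Dirichlet distribution
#   {point: value}                   degenerate point mass
#   {counts: [successes, failures]}  Beta from effectively-treated counts
#   {mean: m, ci: [lo, hi], fit: beta|gamma}  fitted to mean and 95% CI
# plus optional metadata: ci (95% CI as printed), expert (elicited row),
# synthetic (non-study stand-in).

schema_version: 1
price_base: "2012-13"

cure:
  botulinum:
    do:            {beta: [50, 38], ci: [0.464, 0.669]}
    mixed:         {beta: [13.42, 27.36], ci: [0.200, 0.483], expert: true}
    stress:        {beta: [4.32, 25.86], ci: [0.133, 0.375], expert: true}
  neurostim:
    do:            {beta: [245, 159], ci: [0.558, 0.653]}
    stress_mixed:  {beta: [12.36, 27], ci: [0.283, 0.567], expert: true}
  implant:
    do:            {beta: [338, 163], ci: [0.633, 0.715]}
    stress_mixed:  {beta: [7.74, 20.82], ci: [0.233, 0.550], expert: true}
  sling:
    do:            {beta: [5.84, 13], ci: [0.250, 0.350]}
    stress:        {beta: [547, 83], ci: [0.841, 0.894]}
    mixed:         {beta: [1050, 837], ci: [0.534, 0.579]}
  colpo:
    do:            {beta: [5.95, 30.56], ci: [0.153, 0.386], expert: true}
    stress:        {beta: [100, 45], ci: [0.612, 0.762]}
    mixed:         {beta: [40, 42], ci: [0.381, 0.595]}

pathway:
  choose_botox_prior_sling:    {beta: [5.74, 12.53], ci: [0.275, 0.683], expert: true}
  choose_botox_over_neurostim: {beta: [6, 2], ci: [0.421, 0.963], expert: true}
  voiding_difficulty:          {beta: [10, 106], ci: [0.042, 0.143]}
  require_implant:             {beta: [11.23, 5.53], ci: [0.450, 0.880]}
  revision_lt2y:               {beta: [36, 366], ci: [0.064, 0.119]}
  revision_ge2y:               {beta: [282, 573], ci: [0.299, 0.362]}
  maintenance_ge2y:            {beta: [42, 237], ci: [0.111, 0.195]}
  removal:                     {beta: [22, 184], ci: [0.068, 0.152]}

costs:
  urodynamics:         {gamma: [40.65, 9.86], ci: [216, 462]}
  ultrasonography:     {gamma: [1.00, 51.07]}
  botulinum_injection: {gamma: [100.67, 9.06], ci: [704, 1060]}
  neurostim_course:    {gamma: [30.81, 72.08], ci: [1274, 2838]}
  sling:               {gamma: [31.93, 122.69], ci: [2599, 5309]}
  pne:                 {gamma: [258.88, 4.49], ci: [1010, 1293]}
  implant:             {gamma: [57.14, 114.28], ci: [4966, 8347]}
  implant_followup:    {gamma: [32.09, 129.65], ci: [2960, 5831]}
  colposuspension:     {gamma: [31.93, 122.69], ci: [2599, 5309]}
  selfcath_training:   {gamma: [1.00, 84.00]}

utilities:
  do:       {beta: [8.96, 5.98], ci: [0.532, 0.668]}
  stress:   {beta: [18.92, 9.75], ci: [0.514, 0.807]}
  mixed:    {beta: [49.12, 19.29], ci: [0.637, 0.799]}
  normal:   {beta: [22.13, 11.61], ci: [0.558, 0.753]}
  lcvd:     {beta: [11.76, 4.05], ci: [0.547, 0.942]}
  cured:    {beta: [10.69, 0.93], ci: [0.710, 0.990]}
  cured_se: {beta: [304, 45.43], ci: [0.830, 0.900]}

# SYNTHETIC: bladder-wall-thickness index-test accuracy at the 5 mm
# threshold (reference standard: urodynamic detrusor overactivity) and the
# probability of a mixed-incontinence clinical history given each
# urodynamic diagnosis, as pseudo-counts on a 209-woman cohort.
accuracy:
  synthetic: true
  bwt_sensitivity:    {counts: [33, 51]}
  bwt_specificity:    {counts: [104, 21]}
  uds_do_sensitivity: {point: 1.0}
  history_mixed_given:
    do:                  {dirichlet: {mixed: 34, urgency_only: 50}}
    stress:              {dirichlet: {mixed: 27, urgency_only: 9}}
    mixed:               {dirichlet: {mixed: 22, urgency_only: 5}}
    normal:              {dirichlet: {mixed: 17, urgency_only: 25}}
    low_compliance:      {dirichlet: {mixed: 5, urgency_only: 5}}
    voiding_dysfunction: {dirichlet: {mixed: 5, urgency_only: 5}}

# SYNTHETIC: urodynamic diagnosis mix, as counts on a 209-woman cohort.
prevalence:
  synthetic: true
  dirichlet:
    do: 84
    stress: 36
    mixed: 27
    normal: 42
    low_compliance: 10
    voiding_dysfunction: 10

econ:
  discount_rate: 0.035
  horizon_years: 5
  psa_iterations: 10000
  incidence_per_year: 54000
  research_horizon_years: 10
  second_test: true
  botulinum_dropout: [0.20, 0.08]
  botulinum_cure_split: [0.34, 0.52, 0.14]
  wtp_grid_success: {from: 0, to: 100000, by: 500}
  wtp_grid_qaly: {from: 0, to: 50000, by: 250}

# Deterministic scenario settings. The uds_accuracy_low_plus_diary values
# are SYNTHETIC: an imperfect urodynamic detection of detrusor overactivity
# (missed cases managed as mixed incontinence) combined with a clinical
# history sharpened by bladder diaries.
scenario_settings:
  uds_cost_low: {urodynamics_mean: 173}
  sling_cost_double: {factor: 2}
  cure_utility_low: {cured_mean: 0.84}
  uds_accuracy_low_plus_diary:
    uds_do_sensitivity: 0.92
    history_mixed_given:
      do: 0.30
      stress: 0.90
      mixed: 0.90
      normal: 0.40
      low_compliance: 0.50
      voiding_dysfunction: 0.50
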