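# Calibration defaults for the hub-and-spoke transfer-data generator.
# Structural targets: ~200 hospitals in 14 regions, one designated base (hub)
# per region, heavy-tailed in-degree concentrated on hubs, in-degree linear in
# served population (+5.5 partners per million residents), dyadic reciprocity
# 0.21, arc weights spanning <36 to >365 transfers per 3 years, and modest
# year-on-year growth. Record attribute frequencies follow the national
# descriptive profile of ED transfers.
n_regions: 14
hospitals_per_region: [12, 16]
n_base_per_region: 1
population_range: [50000, 350000]        # persons served, non-hub hospitals
base_population_range: [2500000, 4500000] # persons served, base (hub) hospitals
target_slope: 5.5                        # in-degree partners per million residents
in_degree_intercept: 0.5
in_degree_noise_sd: 1.0
hub_attachment_strength: 8.0             # same-region sender preference toward hubs
region_affinity: 2.0                     # same-region sender preference, any receiver
reciprocity_target: 0.21
weight_distribution:                     # discretized log-normal arc weights
  meanlog: 2.2
  sdlog: 1.1
  hub_meanlog: 3.8                       # spoke -> same-region hub arcs
  hub_sdlog: 1.2
reverse_weight_max: 3                    # weak reverse arcs added for reciprocity
years: [2014, 2015, 2016]
yearly_growth: 1.08
age_mean: 55.7
age_sd: 23.8
age_max: 111
reason_missing_rate: 0.022
distributor_quantile: 0.05
distributor_discharge_boost: 0.02
record_attribute_tables:
  sex:
    female: 0.394
    male: 0.606
  time_of_day:
    "07:00-15:00": 0.399
    "15:00-23:00": 0.415
    "23:00-07:00": 0.186
  reason:
    patient_request: 0.430
    specialist_unavailable: 0.332
    capability_problem: 0.233
    other: 0.005
  condition_category:
    acute cerebrovascular disease: 0.085
    pneumonia: 0.048
    intracranial injury: 0.042
    fracture of upper limb: 0.039
    fracture of lower limb: 0.038
    acute myocardial infarction: 0.035
    other: 0.713
  surgery_at_receiver:
    "no": 0.906
    "yes": 0.094
  disposition:
    ward_admission: 0.42177
    ed_observation: 0.29389
    icu_admission: 0.22390
    discharged_outpatient: 0.05509
    transferred_again: 0.00481
    transferred_back: 0.00054
seed: 1
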