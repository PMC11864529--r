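# Replication scenario: ambulance response vs bystander AED retrieval on a
# synthetic city-center street grid.
#
# Stated study parameters: 50 demand points in the central region, a single
# ambulance station, a 300 s coverage budget (2.5 min per walking stretch),
# bystanders at 10 km/h, ambulances at 50 km/h, 18 AED sites selected by
# MCLP. City geometry and the candidate pool are synthetic choices
# (unpublished in the source study): a 24 x 24 lattice of 200 m blocks with
# 10 m node jitter, 30% one-way streets, demand over the central 60% of the
# bounding box, 80 candidate sites, corner station.
city:
  rows: 24
  cols: 24
  block_m: 200
  jitter_m: 10
  oneway_fraction: 0.3
  n_demand: 50
  n_candidates: 80
  n_stations: 1
  center_fraction: 0.6
coverage:
  threshold_s: 300
  bystander_speed_kmh: 10
  ambulance_speed_kmh: 50
station_position: corner
mclp:
  mode: fixed_p
  p: 18
  solver: greedy
stats:
  ci_method: t
  exact_limit: 25
  continuity: false
seed: 1
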