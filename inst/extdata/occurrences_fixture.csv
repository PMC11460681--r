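# Hand-derivable 12-record cleaning fixture for the fixture_world() grid
# (10 x 10 cells of 0.1 deg, origin (0,0); cell (1,1) = water; cell (2,2)
# has a missing vegetation covariate; cell (3,3) [id 23] has activity-season
# length 0). Study period 2000-01-01 .. 2019-12-31.
#
# Manual application of the cleaning cascade, rule by rule:
#   r01 clean (unc 500 m < 1000)            -> SURVIVES, cell (5,5) id 45
#   r02 clean (unc missing, 3 decimals)     -> SURVIVES, cell (6,7) id 57
#   r03 uncertainty 1500 m                  -> rejected: coordinate_uncertainty
#   r04 uncertainty missing, 1 decimal      -> rejected: coordinate_uncertainty
#   r05 fossil specimen                     -> rejected: basis_of_record
#   r06 unknown basis                       -> rejected: basis_of_record
#   r07 date 1999-05-01 (before period)     -> rejected: out_of_period
#   r08 latitude 95 (impossible)            -> rejected: malformed
#   r09 falls in water cell (1,1)           -> rejected: not_on_land
#   r10 falls in cell (2,2), veg missing    -> rejected: missing_covariates
#   r11 falls in cell (3,3), season 0 days  -> rejected: zero_season_length
#   r12 clean, same cell (5,5) as r01       -> SURVIVES (thins with r01)
#
# Expected: 3 survivors (r01, r02, r12); tally malformed 1, out_of_period 1,
# basis_of_record 2, coordinate_uncertainty 2, not_on_land 1,
# missing_covariates 1, zero_season_length 1. Thinned centroids: 2 cells
# (ids 45 and 57). With season_length = NULL (year-round species) r11 also
# survives: 4 survivors, 3 centroids (ids 23, 45, 57).
species,lon,lat,date,coord_uncertainty_m,basis_of_record,coord_decimals
synthetic_species,0.44,0.44,2010-06-01,500,HUMAN_OBSERVATION,2
synthetic_species,0.645,0.545,2005-03-15,,HUMAN_OBSERVATION,3
synthetic_species,0.35,0.35,2012-07-20,1500,HUMAN_OBSERVATION,2
synthetic_species,0.4,0.4,2013-08-02,,HUMAN_OBSERVATION,1
synthetic_species,0.35,0.45,2008-09-10,200,FOSSIL_SPECIMEN,2
synthetic_species,0.45,0.35,2009-10-11,200,UNKNOWN,2
synthetic_species,0.35,0.55,1999-05-01,200,HUMAN_OBSERVATION,2
synthetic_species,0.35,95,2010-01-05,200,HUMAN_OBSERVATION,2
synthetic_species,0.05,0.05,2011-02-06,200,HUMAN_OBSERVATION,2
synthetic_species,0.15,0.15,2014-04-07,200,HUMAN_OBSERVATION,2
synthetic_species,0.25,0.25,2015-05-08,200,HUMAN_OBSERVATION,2
synthetic_species,0.46,0.46,2016-06-09,100,HUMAN_OBSERVATION,2
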