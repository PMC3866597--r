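# version: 1
# Bioclimatic envelope x moisture-ramp parameters for the 13 plant functional
# groups of the simplified vegetation forward model.
# Trapezoid (a,b,c,d): membership 0 below a, rises a->b, 1 on [b,c], falls c->d.
# Moisture ramp: linear from (alpha_lo, v_lo) to (alpha_hi, v_hi), constant outside.
# beta: CO2 sensitivity in (1 + beta*ln(co2/280)); C4 groups near 0.
# moist_forest flags groups whose ramp is non-decreasing in alpha.
group	mtco_a	mtco_b	mtco_c	mtco_d	gdd_a	gdd_b	gdd_c	gdd_d	alpha_lo	v_lo	alpha_hi	v_hi	beta	moist_forest
trop_evergreen	10	15.5	30	35	5000	6500	12000	15000	0.40	0	0.85	1	0.10	1
warm_temp_evergreen	0	4	12	18	2500	3500	6000	8000	0.25	0	0.70	1	0.15	1
temp_deciduous	-12	-6	4	8	1500	2200	4500	6000	0.35	0	0.80	1	0.20	1
cool_conifer	-20	-14	-2	3	800	1200	3000	4200	0.30	0	0.75	1	0.20	1
boreal_conifer	-35	-28	-8	-3	350	600	1800	2600	0.25	0	0.70	1	0.20	1
cool_mixed_forest	-16	-10	2	6	1200	1800	3800	5200	0.30	0	0.80	1	0.20	1
wet_meadow_sedge	-10	-4	10	16	900	1500	5000	7000	0.50	0	0.95	1	0.10	1
cool_steppe_grass	-18	-12	4	9	700	1100	3500	5000	0.05	0.90	0.75	0.10	0.25	0
warm_steppe_grass	2	8	22	28	3000	4500	9000	12000	0.02	0.80	0.60	0.05	0.03	0
desert_shrub	-8	-2	18	26	1500	2500	9000	12000	0.00	1.00	0.35	0.00	0.25	0
tundra_shrub	-40	-32	-10	-5	0	50	700	1100	0.30	0.20	0.70	1	0.15	1
medit_shrub	1	5	14	20	2800	3800	6500	8500	0.08	0.90	0.65	0.25	0.20	0
hot_desert_forb	6	12	28	34	4500	6000	12000	15000	0.00	1.00	0.25	0.00	0.25	0
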