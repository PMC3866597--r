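# AMS radiocarbon determinations for the Akko core (published dating table)
# depth in cm below core top; ages in 14C yr BP with 1-sigma lab error;
# intercept_cal_bp is the published intercept point estimate in cal yr BP
lab_code	depth_cm	c14_age	c14_error	intercept_cal_bp
BETA-337808	80	190	30	170
BETA-337809	101	1310	30	1270
BETA-347581	133	2770	30	2860
BETA-347582	173	4330	30	4860
BETA-337810	215	5200	30	5930
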