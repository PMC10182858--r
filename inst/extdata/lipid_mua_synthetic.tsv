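# Pure lipid (fat) absorption coefficient, near infrared.
# Synthetic smooth compilation: values written to be consistent with
# published mammalian-fat / vegetable-oil absorption measurements
# (van Veen et al. 2005 style), regenerated by hand rather than copied from
# a digital table. The 3rd overtone C-H band maximum is placed at 930 nm
# with the characteristic minimum near 980-1000 nm and the weak 1040 nm
# shoulder. Intended for 900-1075 nm spectral fitting.
# columns: wavelength_nm  mua_cm-1
850	0.0110
855	0.0110
860	0.0120
865	0.0120
870	0.0130
875	0.0140
880	0.0160
885	0.0180
890	0.0210
895	0.0260
900	0.0330
905	0.0430
910	0.0580
915	0.0800
920	0.1060
925	0.1300
930	0.1430
935	0.1350
940	0.1120
945	0.0850
950	0.0630
955	0.0480
960	0.0380
965	0.0320
970	0.0280
975	0.0250
980	0.0230
985	0.0220
990	0.0210
995	0.0210
1000	0.0210
1005	0.0220
1010	0.0240
1015	0.0260
1020	0.0290
1025	0.0330
1030	0.0370
1035	0.0410
1040	0.0440
1045	0.0450
1050	0.0440
1055	0.0420
1060	0.0400
1065	0.0390
1070	0.0390
1075	0.0400
1080	0.0420
1085	0.0450
1090	0.0490
1095	0.0540
1100	0.0600
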