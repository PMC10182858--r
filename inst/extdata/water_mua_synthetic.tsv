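# Pure liquid water absorption coefficient, near infrared.
# Synthetic smooth compilation: values written to be consistent with the
# widely used published water absorption compilations (Hale & Querry 1973;
# Segelstein 1981) at 25 C, but regenerated by hand rather than copied from
# a digital table. Band maximum of the 2nd overtone O-H combination band is
# placed at 975 nm. Intended for 900-1075 nm spectral fitting; accurate to
# roughly 5-10% of the literature values across 850-1100 nm.
# columns: wavelength_nm  mua_cm-1
850	0.0430
855	0.0450
860	0.0470
865	0.0490
870	0.0520
875	0.0550
880	0.0580
885	0.0610
890	0.0640
895	0.0660
900	0.0680
905	0.0750
910	0.0850
915	0.0980
920	0.1150
925	0.1380
930	0.1680
935	0.2050
940	0.2670
945	0.3100
950	0.3520
955	0.3920
960	0.4250
965	0.4500
970	0.4660
975	0.4750
980	0.4710
985	0.4570
990	0.4370
995	0.4120
1000	0.3630
1005	0.3400
1010	0.3160
1015	0.2920
1020	0.2680
1025	0.2460
1030	0.2250
1035	0.2060
1040	0.1900
1045	0.1760
1050	0.1640
1055	0.1540
1060	0.1470
1065	0.1420
1070	0.1390
1075	0.1380
1080	0.1390
1085	0.1420
1090	0.1470
1095	0.1540
1100	0.1630
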