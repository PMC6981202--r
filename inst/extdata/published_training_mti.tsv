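gene	group	logfc	fdr
GUCY1B1	aerobic_hly	0.26	7.8e-03
GUCY1B1	aerobic_mti	0.09	9.7e-01
GUCY1B1	resistance_hly	0.11	2.0e-01
GUCY1B1	resistance_mti	0.02	1.0e+00
KANSL3	aerobic_hly	-0.09	7.8e-03
KANSL3	aerobic_mti	-0.04	1.0e+00
KANSL3	resistance_hly	0.03	6.9e-01
KANSL3	resistance_mti	0.01	1.0e+00
ARNT	aerobic_hly	-0.10	7.8e-03
ARNT	aerobic_mti	-0.02	1.0e+00
ARNT	resistance_hly	0.01	9.3e-01
ARNT	resistance_mti	-0.05	1.0e+00
TOP2B	aerobic_hly	-0.20	7.1e-03
TOP2B	aerobic_mti	-0.04	1.0e+00
TOP2B	resistance_hly	-0.09	5.5e-02
TOP2B	resistance_mti	0.00	1.0e+00
IGIP	aerobic_hly	-0.19	7.1e-03
IGIP	aerobic_mti	-0.03	1.0e+00
IGIP	resistance_hly	-0.10	1.6e-01
IGIP	resistance_mti	-0.03	1.0e+00
COL6A6	aerobic_hly	0.24	7.9e-02
COL6A6	aerobic_mti	0.04	8.1e-01
COL6A6	resistance_hly	0.36	6.2e-04
COL6A6	resistance_mti	-0.03	1.0e+00
APLNR	aerobic_hly	0.22	3.9e-01
APLNR	aerobic_mti	0.18	7.8e-01
APLNR	resistance_hly	0.36	6.5e-03
APLNR	resistance_mti	-0.01	1.0e+00
COL4A2	aerobic_hly	0.53	2.8e-01
COL4A2	aerobic_mti	0.33	1.3e-01
COL4A2	resistance_hly	0.53	9.7e-04
COL4A2	resistance_mti	0.19	1.0e+00
PTGDS	aerobic_hly	0.09	8.2e-01
PTGDS	aerobic_mti	0.07	1.0e+00
PTGDS	resistance_hly	0.37	5.7e-04
PTGDS	resistance_mti	0.03	1.0e+00
ABCG1	aerobic_hly	-0.07	8.2e-01
ABCG1	aerobic_mti	-0.03	1.0e+00
ABCG1	resistance_hly	0.29	2.5e-03
ABCG1	resistance_mti	-0.02	1.0e+00
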