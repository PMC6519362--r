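chrS	1000	1007	M01
chrS	6000	6008	M02
chrS	11000	11009	M03
chrS	16000	16010	M04
chrS	21000	21011	M05
chrS	26000	26012	M06
chrS	31000	31007	M07
chrS	36000	36008	M08
chrS	41000	41009	M09
chrS	46000	46010	M10
chrS	51000	51011	M11
chrS	56000	56012	M12
chrS	61000	61007	M13
chrS	66000	66008	M14
chrS	71000	71009	M15
chrS	76000	76010	M16
chrS	81000	81011	M17
chrS	86000	86012	M18
chrS	91000	91007	M19
chrS	96000	96008	M20
chrS	101000	101009	M21
chrS	106000	106010	M22
chrS	111000	111011	M23
chrS	116000	116012	M24
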