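label	study	or	ci_low	ci_high	pooled_or	pooled_ci_low	pooled_ci_high
rs11568820	studyA	1.05	0.88	1.24	0.96	0.83	1.12
rs11568820	studyB	0.90	0.78	1.04	0.96	0.83	1.12
rs1544410	studyA	1.09	0.95	1.25	1.02	0.92	1.12
rs1544410	studyB	0.98	0.89	1.08	1.02	0.92	1.12
rs2228570	studyA	1.09	0.95	1.25	1.09	1.00	1.19
rs2228570	studyB	1.09	0.97	1.23	1.09	1.00	1.19
rs731236	studyA	1.12	0.97	1.29	1.07	0.96	1.20
rs731236	studyB	1.02	0.87	1.20	1.07	0.96	1.20
rs7975232	studyA	1.17	1.02	1.36	1.12	1.01	1.25
rs7975232	studyB	1.07	0.92	1.25	1.12	1.01	1.25
rs4588	studyA	0.99	0.85	1.15	0.96	0.88	1.05
rs4588	studyB	0.95	0.85	1.05	0.96	0.88	1.05
rs7041	studyA	0.95	0.83	1.10	0.92	0.85	0.99
rs7041	studyB	0.90	0.82	0.99	0.92	0.85	0.99
rs10741657	studyA	0.96	0.84	1.11	1.05	0.89	1.24
rs10741657	studyB	1.14	1.01	1.30	1.05	0.89	1.24
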