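population	haplotype	count
GXLC	H6	2
GXLC	H11	2
GXLC	H13	1
GXLC	H18	1
GXNN	H14	8
GXNN	H15	2
GXNN	H16	1
GXNN	H17	1
GDDQ	H11	3
GDDQ	H22	2
GDDQ	H23	1
GDDQ	H24	1
GDDQ	H25	1
YNWS	H1	1
YNWS	H2	3
YNWS	H3	1
YNWS	H4	1
GXBS	H46	1
GXBS	H47	5
GXBS	H48	4
GDXN	H2	2
GDXN	H7	2
YNSL	H2	4
YNSL	H41	2
FJSH	H38	5
FJSH	H39	1
FJSH	H40	3
GZXY	H6	1
GZXY	H19	3
GZXY	H20	1
FJWP	H11	3
FJWP	H18	2
FJWP	H22	3
FJWP	H35	1
FJWP	H36	1
FJWP	H37	1
GXQZ	H5	1
GXQZ	H6	2
GXQZ	H8	8
GXQZ	H9	2
GXQZ	H10	1
GXQZ	H11	4
GXQZ	H12	1
GXQZ	H13	1
YNYR	H4	3
YNYR	H5	1
YNYR	H6	7
YNYR	H7	1
GZGY	H5	1
GZGY	H6	3
GZGY	H18	1
GZGY	H19	3
GZHZ	H6	3
GZHZ	H11	3
GZHZ	H21	1
JXYC	H5	1
JXYC	H6	1
JXYC	H22	4
JXYC	H23	4
JXYC	H45	2
JXGA	H2	4
JXGA	H3	1
JXGA	H41	2
JXGA	H42	2
JXGA	H43	1
JXGA	H44	1
ZJJS	H27	3
ZJJS	H28	2
ZJJS	H29	4
ZJJS	H30	1
ZJQX	H1	1
ZJQX	H2	6
ZJQX	H3	3
ZJQX	H26	1
ZJLX	H11	2
ZJLX	H18	1
ZJLX	H31	3
ZJLX	H32	1
ZJLX	H33	1
ZJLX	H34	1
SCLX	H2	4
SCHY	H6	3
SCHY	H9	1
SCHY	H22	2
SCHY	H23	1
SCHY	H37	1
AHQS	H2	10
AHQS	H3	1
AHQS	H46	1
HBCD	H49	15
HBCD	H50	8
HBCD	H51	12
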