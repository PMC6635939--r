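population	locality	lat	lon	n	region
GXLC	Luchuan, Guangxi	22.19	110.16	6	East
GXNN	Naning, Guangxi	22.49	108.21	12	Southwest
GDDQ	Deqing, Guangdong	23.15	111.77	8	East
YNWS	Wenshan, Yunnan	23.22	104.15	6	Southwest
GXBS	Baise, Guangxi	23.53	106.37	10	Southwest
GDXN	Xingning, Guangdong	24.15	115.73	4	East
YNSL	Shilin, Yunnan	24.45	103.16	6	Southwest
FJSH	Shanghang, Fujian	25.02	116.25	9	East
GZXY	Xingyi, Guizhou	25.05	104.54	5	Southwest
FJWP	Wuping, Fujian	25.10	116.10	11	East
GXQZ	Quanzhou, Guangxi	25.55	111.04	20	East
YNYR	Yongren, Yunnan	26.03	101.40	12	Southwest
GZGY	Guiyang, Guizhou	26.38	106.37	8	Southwest
GZHZ	Hezhang, Guizhou	27.07	104.43	7	Southwest
JXYC	Yichun, Jiangxi	27.47	114.23	12	East
JXGA	Gaoan, Jiangxi	28.25	115.22	11	East
ZJJS	Jiangshan, Zhejiang	28.44	118.37	10	East
ZJQX	Quxian, Zhejiang	29.03	119.11	11	East
ZJLX	Lanxi, Zhejiang	29.12	119.28	9	East
SCLX	Luxian, Sichuan	29.15	105.38	4	Southwest
SCHY	Huaying, Sichuan	30.38	106.77	8	Southwest
AHQS	Qianshan, Anhui	30.57	116.34	12	East
HBCD	Chengde, Hebei	40.59	118.53	35	East
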