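protein	start	end	sequence	missed_cleavages
ALDOB_SYN	9	31	MQAQMALGVFNKMNNFNFESGMK	1
ALDOB_SYN	40	58	GTDFANEKAFASTVDSAGK	1
ALDOB_SYN	59	84	TFNMANLIENDKTQSALSKTMIMNAK	2
ALDOB_SYN	85	92	FTSMMASK	0
ALDOB_SYN	105	115	MSMFMSGIMAK	0
ALDOB_SYN	116	125	AMLSTAATNK	0
ALDOB_SYN	152	159	QFQNSNEK	0
ALDOB_SYN	171	177	IIGSAEK	0
ALDOB_SYN	178	190	MNSWDSAEAFLMK	0
ALDOB_SYN	204	213	VALNGANDQK	0
ALDOB_SYN	214	225	EIITGAVGSSSK	0
ALDOB_SYN	236	243	DTEGAINK	0
ALDOB_SYN	244	259	YTPLEVAMATVTALRR	1
ALDOB_SYN	260	269	GTMTTMSMTK	0
ALDOB_SYN	270	277	SGQFDSMK	0
ALDOB_SYN	278	296	GFNGAGTSNMKEDINQTNK	1
ALDOB_SYN	297	315	MIVGIVERALQASALSAWK	1
ALDOB_SYN	342	361	AEINLSTIIDKWVFEDASSR	1
ALDOC_SYN	9	20	MQAQAALGFFNK	0
ALDOC_SYN	21	31	MNNFNLEIGFK	0
ALDOC_SYN	40	47	IEDFEAEK	0
ALDOC_SYN	78	84	TMEMGQK	0
ALDOC_SYN	85	92	FFSMMNGK	0
ALDOC_SYN	93	104	GMNAQTGEQASK	0
ALDOC_SYN	116	125	NTLSTAATNK	0
ALDOC_SYN	160	170	MSTSWGGDEAK	0
ALDOC_SYN	178	190	MGTWDSATAFLHK	0
ALDOC_SYN	214	225	VGITGIVGSSGK	0
ALDOC_SYN	236	243	DTEGAINK	0
ALDOC_SYN	260	269	HTMTTMSMTK	0
ALDOC_SYN	270	277	SGQFDSSK	0
ALDOC_SYN	289	296	EDIGGTNK	0
ALDOC_SYN	297	304	MLEHIVER	0
ALDOC_SYN	305	322	ALQASALSAWRGVKENEK	2
ALDOC_SYN	323	334	DESVHVWNTTIK	0
ALDOC_SYN	353	361	WVNEDASSR	0
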