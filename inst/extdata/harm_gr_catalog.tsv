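gene_id	subfamily	bitter_type	pseudogene	partial
HarmGR1	co2	not_bitter	FALSE	none
HarmGR2	co2	not_bitter	FALSE	none
HarmGR3	co2	not_bitter	FALSE	none
HarmGR4	sugar	not_bitter	FALSE	none
HarmGR5	sugar	not_bitter	FALSE	none
HarmGR6	sugar	not_bitter	FALSE	none
HarmGR7	sugar	not_bitter	FALSE	none
HarmGR8	sugar	not_bitter	FALSE	none
HarmGR9	gr43a_like	not_bitter	FALSE	none
HarmGR10	sugar	not_bitter	FALSE	none
HarmGR11	sugar	not_bitter	FALSE	none
HarmGR12	sugar	not_bitter	FALSE	none
HarmGR13	gr43a_like	not_bitter	FALSE	none
HarmGR14	bitter	unknown	FALSE	none
HarmGR15	bitter	unknown	FALSE	none
HarmGR16	bitter	unknown	FALSE	none
HarmGR17	bitter	unknown	FALSE	none
HarmGR18	bitter	unknown	FALSE	none
HarmGR19	bitter	unknown	FALSE	none
HarmGR20	bitter	unknown	FALSE	none
HarmGR21	bitter	unknown	FALSE	none
HarmGR22	bitter	unknown	FALSE	none
HarmGR23	bitter	unknown	FALSE	none
HarmGR24	bitter	unknown	FALSE	none
HarmGR25	bitter	unknown	FALSE	none
HarmGR26	bitter	unknown	FALSE	none
HarmGR27	bitter	unknown	FALSE	none
HarmGR28	bitter	unknown	FALSE	none
HarmGR29	bitter	unknown	FALSE	none
HarmGR30	bitter	unknown	FALSE	none
HarmGR31	bitter	unknown	FALSE	none
HarmGR32	bitter	unknown	FALSE	none
HarmGR33	bitter	unknown	FALSE	none
HarmGR34	bitter	unknown	FALSE	none
HarmGR35	bitter	unknown	FALSE	none
HarmGR36	bitter	unknown	FALSE	none
HarmGR37	bitter	unknown	FALSE	none
HarmGR38	bitter	unknown	FALSE	none
HarmGR39	bitter	unknown	FALSE	none
HarmGR40	bitter	unknown	FALSE	none
HarmGR41	bitter	unknown	FALSE	none
HarmGR42	bitter	unknown	FALSE	none
HarmGR43	bitter	unknown	FALSE	none
HarmGR44	bitter	unknown	FALSE	unspecified
HarmGR45	bitter	unknown	FALSE	unspecified
HarmGR46	bitter	unknown	FALSE	none
HarmGR47	bitter	unknown	FALSE	none
HarmGR48	bitter	unknown	FALSE	none
HarmGR49	bitter	unknown	FALSE	none
HarmGR50	bitter	unknown	FALSE	none
HarmGR51	bitter	unknown	FALSE	none
HarmGR52	bitter	unknown	FALSE	none
HarmGR53	bitter	unknown	FALSE	none
HarmGR54	bitter	unknown	FALSE	none
HarmGR55	bitter	unknown	FALSE	none
HarmGR56	bitter	unknown	FALSE	none
HarmGR57	bitter	unknown	TRUE	none
HarmGR58	bitter	unknown	FALSE	none
HarmGR59	bitter	unknown	FALSE	none
HarmGR60	bitter	unknown	FALSE	none
HarmGR61	bitter	unknown	FALSE	none
HarmGR62	bitter	unknown	FALSE	none
HarmGR63	bitter	unknown	FALSE	unspecified
HarmGR64	bitter	unknown	FALSE	none
HarmGR65	bitter	unknown	FALSE	none
HarmGR66	bitter	unknown	FALSE	none
HarmGR67	bitter	unknown	FALSE	none
HarmGR68	bitter	unknown	FALSE	none
HarmGR69	bitter	unknown	FALSE	none
HarmGR70	bitter	unknown	FALSE	none
HarmGR71	bitter	unknown	FALSE	none
HarmGR72	bitter	unknown	FALSE	none
HarmGR73	bitter	unknown	FALSE	none
HarmGR74	bitter	unknown	FALSE	none
HarmGR75	bitter	unknown	FALSE	none
HarmGR76	bitter	unknown	FALSE	none
HarmGR77	bitter	unknown	FALSE	none
HarmGR78	bitter	unknown	FALSE	unspecified
HarmGR79	bitter	unknown	FALSE	none
HarmGR80	bitter	unknown	FALSE	none
HarmGR81	bitter	unknown	FALSE	none
HarmGR82	bitter	unknown	FALSE	none
HarmGR83	bitter	unknown	FALSE	none
HarmGR84	bitter	unknown	FALSE	none
HarmGR85	bitter	unknown	FALSE	unspecified
HarmGR86	bitter	unknown	FALSE	none
HarmGR87	bitter	unknown	FALSE	none
HarmGR88	bitter	unknown	FALSE	unspecified
HarmGR89	bitter	unknown	FALSE	none
HarmGR90	bitter	unknown	FALSE	none
HarmGR91	bitter	unknown	FALSE	none
HarmGR92	bitter	unknown	FALSE	none
HarmGR93	bitter	unknown	FALSE	none
HarmGR94	bitter	unknown	FALSE	none
HarmGR95	bitter	unknown	FALSE	none
HarmGR96	bitter	unknown	FALSE	none
HarmGR97	bitter	unknown	FALSE	none
HarmGR98	bitter	unknown	FALSE	none
HarmGR99	bitter	unknown	FALSE	none
HarmGR100	bitter	unknown	FALSE	none
HarmGR101	bitter	unknown	FALSE	none
HarmGR102	bitter	unknown	FALSE	none
HarmGR103	bitter	unknown	FALSE	unspecified
HarmGR104	bitter	unknown	FALSE	none
HarmGR105	bitter	unknown	FALSE	none
HarmGR106	bitter	unknown	FALSE	unspecified
HarmGR107	bitter	unknown	FALSE	none
HarmGR108	bitter	unknown	FALSE	none
HarmGR109	bitter	unknown	FALSE	none
HarmGR110	bitter	unknown	FALSE	none
HarmGR111	bitter	unknown	FALSE	none
HarmGR112	bitter	unknown	FALSE	none
HarmGR113	bitter	unknown	FALSE	none
HarmGR114	bitter	unknown	FALSE	none
HarmGR115	bitter	unknown	FALSE	none
HarmGR116	bitter	unknown	FALSE	none
HarmGR117	bitter	unknown	FALSE	none
HarmGR118	bitter	unknown	FALSE	unspecified
HarmGR119	bitter	unknown	FALSE	none
HarmGR120	bitter	unknown	FALSE	none
HarmGR121	bitter	unknown	FALSE	none
HarmGR122	bitter	unknown	FALSE	none
HarmGR123	bitter	unknown	FALSE	unspecified
HarmGR124	bitter	unknown	FALSE	none
HarmGR125	bitter	unknown	FALSE	none
HarmGR126	bitter	unknown	FALSE	none
HarmGR127	bitter	unknown	FALSE	none
HarmGR128	bitter	unknown	FALSE	none
HarmGR129	bitter	unknown	FALSE	none
HarmGR130	bitter	unknown	FALSE	none
HarmGR131	bitter	unknown	FALSE	none
HarmGR132	bitter	unknown	FALSE	none
HarmGR133	bitter	unknown	FALSE	none
HarmGR134	bitter	unknown	FALSE	none
HarmGR135	bitter	unknown	FALSE	none
HarmGR136	bitter	unknown	FALSE	none
HarmGR137	bitter	unknown	FALSE	none
HarmGR138	bitter	unknown	FALSE	none
HarmGR139	bitter	unknown	FALSE	none
HarmGR140	bitter	unknown	FALSE	none
HarmGR141	bitter	unknown	FALSE	none
HarmGR142	bitter	unknown	FALSE	none
HarmGR143	bitter	unknown	FALSE	none
HarmGR144	bitter	unknown	FALSE	none
HarmGR145	bitter	unknown	FALSE	none
HarmGR146	bitter	unknown	FALSE	none
HarmGR147	bitter	unknown	FALSE	none
HarmGR148	bitter	unknown	FALSE	none
HarmGR149	bitter	unknown	FALSE	none
HarmGR150	bitter	unknown	FALSE	none
HarmGR151	bitter	unknown	FALSE	unspecified
HarmGR152	bitter	unknown	FALSE	none
HarmGR153	bitter	unknown	FALSE	none
HarmGR154	bitter	unknown	FALSE	none
HarmGR155	bitter	unknown	FALSE	none
HarmGR156	bitter	unknown	FALSE	none
HarmGR157	bitter	unknown	FALSE	none
HarmGR158	bitter	unknown	TRUE	none
HarmGR159	bitter	unknown	FALSE	none
HarmGR160	bitter	unknown	FALSE	none
HarmGR161	bitter	unknown	FALSE	none
HarmGR162	bitter	unknown	FALSE	none
HarmGR163	bitter	unknown	FALSE	none
HarmGR164	bitter	unknown	FALSE	none
HarmGR165	bitter	unknown	FALSE	none
HarmGR166	bitter	unknown	FALSE	none
HarmGR167	bitter	unknown	FALSE	none
HarmGR168	bitter	unknown	FALSE	none
HarmGR169	bitter	unknown	FALSE	none
HarmGR170	bitter	unknown	FALSE	none
HarmGR171	bitter	unknown	FALSE	none
HarmGR172	bitter	unknown	FALSE	none
HarmGR173	bitter	unknown	FALSE	none
HarmGR174	bitter	unknown	FALSE	none
HarmGR175	bitter	unknown	FALSE	none
HarmGR176	bitter	unknown	FALSE	none
HarmGR177	bitter	unknown	FALSE	none
HarmGR178	bitter	unknown	FALSE	none
HarmGR179	bitter	unknown	TRUE	none
HarmGR180	bitter	unknown	FALSE	none
HarmGR181	bitter	unknown	FALSE	none
HarmGR182	bitter	unknown	FALSE	none
HarmGR183	bitter	unknown	FALSE	none
HarmGR184	bitter	unknown	FALSE	none
HarmGR185	bitter	unknown	FALSE	unspecified
HarmGR186	bitter	unknown	FALSE	none
HarmGR187	bitter	unknown	FALSE	none
HarmGR188	bitter	unknown	FALSE	none
HarmGR189	bitter	unknown	FALSE	none
HarmGR190	bitter	unknown	FALSE	none
HarmGR191	bitter	unknown	FALSE	none
HarmGR192	bitter	unknown	FALSE	none
HarmGR193	bitter	unknown	TRUE	none
HarmGR194	bitter	unknown	FALSE	unspecified
HarmGR195	bitter	unknown	FALSE	none
HarmGR196	bitter	unknown	FALSE	none
HarmGR197	bitter	unknown	FALSE	none
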