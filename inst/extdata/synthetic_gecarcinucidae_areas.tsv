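taxon	areas
sp01	A
sp02	A
sp03	A
sp04	B
sp05	A
sp06	A
sp07	A
sp08	A
sp09	B
sp10	A
sp11	A
sp12	A
sp13	AB
sp14	A
sp15	A
sp16	A
sp17	A
sp18	A
sp19	A
sp20	A
sp21	A
sp22	A
sp23	A
sp24	A
sp25	A
sp26	A
sp27	A
sp28	A
sp29	A
sp30	A
sp31	A
sp32	A
sp33	A
sp34	A
sp35	AB
sp36	A
sp37	A
sp38	A
sp39	A
sp40	A
sp41	A
sp42	A
sp43	A
sp44	A
sp45	A
sp46	A
sp47	A
sp48	A
sp49	A
sp50	A
sp51	A
sp52	A
sp53	A
sp54	A
sp55	A
sp56	A
sp57	A
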