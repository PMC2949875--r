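(((((sp40:18.6490574007731,((sp13:13.7699828989978,(sp48:9.68057497844699,(((sp10:0.624453086027464,sp16:0.624453086027464):4.99098741373513,sp21:5.61544049976259):2.53519352267845,sp53:8.15063402244104):1.52994095600596):4.08940792055083):3.07702905548559,(sp54:15.6335381453409,sp33:15.6335381453409):1.21347380914248):1.80204544628967):1.08273768695685,(sp23:0.376290541029183,(sp19:0.281048787147269,sp55:0.281048787147269):0.0952417538819134):19.3555045467007):14.0437291231562,((((sp34:6.82108825204063,sp15:6.82108825204063):2.959394245884,sp22:9.78048249792463):18.7373849205592,(((sp07:3.44200178730802,(sp44:0.704664026411583,sp49:0.704664026411583):2.73733776089643):11.2893859244753,(sp12:13.0147506989474,sp42:13.0147506989474):1.71663701283585):6.27749533033295,(sp03:12.4023497020004,(sp57:1.03832687720296,sp46:1.03832687720296):11.3640228247975):8.6065333401158):7.50898437636755):3.95398398147705,((sp47:6.12474983181163,(sp31:1.10320173469366,sp56:1.10320173469366):5.02154809711797):9.42143748692189,((sp24:0.216492688698778,sp45:0.216492688698778):1.74776175052011,sp52:1.96425443921888):13.5819328795146):16.9256640812273):1.30367281092529):4.15041232503735,((sp29:12.4393874256648,((sp05:8.16087284442735,sp18:8.16087284442735):2.05792932831475,sp20:10.2188021727421):2.22058525292265):8.60927264458811,(sp06:15.8263514495127,((sp17:12.9843439244299,(sp01:3.82331384753884,(sp37:3.50707684040494,sp51:3.50707684040494):0.316237007133904):9.16103007689109):2.44914740601725,(sp14:9.96656519539475,(sp28:8.25163292188218,((((sp41:1.28692903010882,sp26:1.28692903010882):1.01585103526158,sp32:2.3027800653704):4.62133348507701,sp38:6.92411355044741):1.17319737514719,((sp50:4.41965763310556,(sp30:4.266874723518,((sp27:2.12979783622336,sp36:2.12979783622336):0.477559608369662,sp35:2.60735744459303):1.65951727892497):0.152782909587562):1.82665926027241,sp43:6.24631689337798):1.85099403221662):0.15432199628758):1.71493227351257):5.46692613505244):0.392860119065513):5.22230862074017):16.8772764656706):9.30406346407653,(((sp11:3.91623507068746,(sp02:3.74449479338257,sp25:3.74449479338257):0.171740277304882):7.88336124174152,sp08:11.799596312429):7.60572961807265,(sp09:18.8060124949628,(sp04:0.182168450244168,sp39:0.182168450244168):18.6238440447186):0.599313435538868):27.8246740694984);
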