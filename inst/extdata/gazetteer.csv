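country,name,case_sensitive
US,united states,FALSE
US,united states of america,FALSE
US,usa,FALSE
US,US,TRUE
US,america,FALSE
US,washington dc,FALSE
US,new york,FALSE
US,new york city,FALSE
US,nyc,FALSE
US,los angeles,FALSE
US,chicago,FALSE
US,houston,FALSE
US,philadelphia,FALSE
US,phoenix,FALSE
US,san antonio,FALSE
US,san diego,FALSE
US,dallas,FALSE
US,san francisco,FALSE
US,seattle,FALSE
US,boston,FALSE
US,miami,FALSE
US,atlanta,FALSE
US,denver,FALSE
US,austin,FALSE
US,portland,FALSE
US,nashville,FALSE
US,baltimore,FALSE
US,minneapolis,FALSE
US,detroit,FALSE
US,alabama,FALSE
US,alaska,FALSE
US,arizona,FALSE
US,arkansas,FALSE
US,california,FALSE
US,colorado,FALSE
US,connecticut,FALSE
US,delaware,FALSE
US,florida,FALSE
US,georgia,FALSE
US,hawaii,FALSE
US,idaho,FALSE
US,illinois,FALSE
US,indiana,FALSE
US,iowa,FALSE
US,kansas,FALSE
US,kentucky,FALSE
US,louisiana,FALSE
US,maine,FALSE
US,maryland,FALSE
US,massachusetts,FALSE
US,michigan,FALSE
US,minnesota,FALSE
US,mississippi,FALSE
US,missouri,FALSE
US,montana,FALSE
US,nebraska,FALSE
US,nevada,FALSE
US,new hampshire,FALSE
US,new jersey,FALSE
US,new mexico,FALSE
US,north carolina,FALSE
US,north dakota,FALSE
US,ohio,FALSE
US,oklahoma,FALSE
US,oregon,FALSE
US,pennsylvania,FALSE
US,rhode island,FALSE
US,south carolina,FALSE
US,south dakota,FALSE
US,tennessee,FALSE
US,texas,FALSE
US,utah,FALSE
US,vermont,FALSE
US,virginia,FALSE
US,washington,FALSE
US,west virginia,FALSE
US,wisconsin,FALSE
US,wyoming,FALSE
US,AL,TRUE
US,AK,TRUE
US,AZ,TRUE
US,AR,TRUE
US,CO,TRUE
US,CT,TRUE
US,DE,TRUE
US,FL,TRUE
US,GA,TRUE
US,HI,TRUE
US,ID,TRUE
US,IL,TRUE
US,IN,TRUE
US,IA,TRUE
US,KS,TRUE
US,KY,TRUE
US,LA,TRUE
US,MA,TRUE
US,MD,TRUE
US,MI,TRUE
US,MN,TRUE
US,MO,TRUE
US,MS,TRUE
US,MT,TRUE
US,NC,TRUE
US,ND,TRUE
US,NH,TRUE
US,NJ,TRUE
US,NM,TRUE
US,NV,TRUE
US,NY,TRUE
US,OH,TRUE
US,OK,TRUE
US,OR,TRUE
US,PA,TRUE
US,RI,TRUE
US,SC,TRUE
US,SD,TRUE
US,TN,TRUE
US,TX,TRUE
US,UT,TRUE
US,VA,TRUE
US,VT,TRUE
US,WA,TRUE
US,WI,TRUE
US,WV,TRUE
US,WY,TRUE
US,DC,TRUE
GB,united kingdom,FALSE
GB,uk,FALSE
GB,great britain,FALSE
GB,britain,FALSE
GB,england,FALSE
GB,scotland,FALSE
GB,wales,FALSE
GB,northern ireland,FALSE
GB,london,FALSE
GB,manchester,FALSE
GB,birmingham,FALSE
GB,liverpool,FALSE
GB,leeds,FALSE
GB,glasgow,FALSE
GB,edinburgh,FALSE
GB,cardiff,FALSE
GB,belfast,FALSE
GB,bristol,FALSE
GB,sheffield,FALSE
GB,newcastle,FALSE
GB,nottingham,FALSE
GB,yorkshire,FALSE
GB,oxford,FALSE
GB,cambridge,FALSE
CA,canada,FALSE
CA,ontario,FALSE
CA,quebec,FALSE
CA,british columbia,FALSE
CA,alberta,FALSE
CA,manitoba,FALSE
CA,saskatchewan,FALSE
CA,nova scotia,FALSE
CA,new brunswick,FALSE
CA,newfoundland,FALSE
CA,newfoundland and labrador,FALSE
CA,prince edward island,FALSE
CA,yukon,FALSE
CA,nunavut,FALSE
CA,northwest territories,FALSE
CA,toronto,FALSE
CA,montreal,FALSE
CA,vancouver,FALSE
CA,ottawa,FALSE
CA,calgary,FALSE
CA,edmonton,FALSE
CA,winnipeg,FALSE
CA,halifax,FALSE
CA,victoria,FALSE
CA,mississauga,FALSE
CA,ON,TRUE
CA,QC,TRUE
CA,BC,TRUE
CA,AB,TRUE
CA,MB,TRUE
CA,SK,TRUE
CA,NS,TRUE
CA,NB,TRUE
CA,NL,TRUE
CA,PE,TRUE
CA,YT,TRUE
CA,NT,TRUE
CA,NU,TRUE
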